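#' Configuration for the synthetic-data generators
#'
#' The synthetic generators are deliberately *not* the mechanistic
#' simulator: they plant known regression-scale interaction coefficients
#' (`b_TD`, `b_BU`) into simple multiplicative updates, so that the whole
#' analysis chain (aggregation, transition tables, regressions, bootstrap
#' null) can be checked against exactly known ground truth. The mechanistic
#' test data come from [run_ensemble()] instead.
#'
#' @param n_patches number of patches; a power of 3 keeps the data
#'   compatible with a fractal layout (default 81)
#' @param n_rounds number of experimental rounds (default 4)
#' @param n_days total daily samples across all rounds (default 34)
#' @param b_TD planted top-down coefficient: the per-interval herbivore
#'   *decline* `log(H_t+1) - log(H_{t+1}+1)` contains the term
#'   `b_TD * (P_t + P_{t+1})/2` (log-ratio units per predator). The default
#'   0 gives the no-interaction (calibration) structure; non-zero values
#'   are dials for parameter-recovery studies. Because the planted term is
#'   exactly linear and compounds daily, large `|b_TD|` together with
#'   large predator counts drives herbivore counts over many orders of
#'   magnitude; pair strong coefficients with `b_BU = 0` (and vice versa)
#'   to avoid runaway feedback between the two planted couplings
#' @param b_BU planted bottom-up coefficient: the per-interval predator
#'   increase contains `b_BU * H_t` (log-ratio units per herbivore);
#'   default 0, see `b_TD`
#' @param predator_trend global multiplicative predator trend per day
#'   (< 1: the decline seen when predators steadily leave an open system)
#' @param herbivore_trend global multiplicative herbivore trend per day
#' @param restock_total_threshold within a round, if the total predator
#'   count is 0, or at most this value for two consecutive days, predators
#'   are re-stocked
#' @param restock_count number of patches receiving one predator at each
#'   (re-)stocking
#' @param daily_additions predators added every day to the patches at the
#'   centre of the array (split over two central patches)
#' @param noise_sd standard deviation of the lognormal process noise
#' @param H_init_mean mean initial herbivore count per patch
#' @param occ_H,occ_P initial presence probability per patch (field-like
#'   generator)
#' @param col_H,col_P per-interval colonization probability of an empty
#'   patch (field-like)
#' @param ext_H,ext_P per-interval extinction probability of an occupied
#'   patch (field-like)
#' @param lambda_H,lambda_P mean abundance (above 1) when present
#'   (field-like), and the Poisson means of the exchangeable generator
#' @param n_dates,interval_days field-like sampling schedule (default 20
#'   dates every 3 days, i.e. a 59-day survey slightly denser than two
#'   months)
#' @param seed optional integer seed stored in the config
#' @return an object of class `pp_synth_config`
#' @export
synth_config <- function(n_patches = 81L,
                         n_rounds = 4L,
                         n_days = 34L,
                         b_TD = 0,
                         b_BU = 0,
                         predator_trend = 0.9,
                         herbivore_trend = 0.98,
                         restock_total_threshold = 1L,
                         restock_count = 9L,
                         daily_additions = 2L,
                         noise_sd = 0.3,
                         H_init_mean = 30,
                         occ_H = 0.85, col_H = 0.3, ext_H = 0.05,
                         occ_P = 0.15, col_P = 0.05, ext_P = 0.5,
                         lambda_H = 40, lambda_P = 0.5,
                         n_dates = 20L, interval_days = 3L,
                         seed = NULL) {
  cfg <- list(
    n_patches = as.integer(n_patches), n_rounds = as.integer(n_rounds),
    n_days = as.integer(n_days), b_TD = b_TD, b_BU = b_BU,
    predator_trend = predator_trend, herbivore_trend = herbivore_trend,
    restock_total_threshold = as.integer(restock_total_threshold),
    restock_count = as.integer(restock_count),
    daily_additions = as.integer(daily_additions),
    noise_sd = noise_sd, H_init_mean = H_init_mean,
    occ_H = occ_H, col_H = col_H, ext_H = ext_H,
    occ_P = occ_P, col_P = col_P, ext_P = ext_P,
    lambda_H = lambda_H, lambda_P = lambda_P,
    n_dates = as.integer(n_dates), interval_days = as.integer(interval_days),
    seed = seed
  )
  if (cfg$noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (cfg$n_patches < 1) stop("`n_patches` must be positive")
  if (cfg$n_rounds < 1 || cfg$n_days < cfg$n_rounds) {
    stop("need at least one day per round")
  }
  if (cfg$restock_count > cfg$n_patches) {
    stop("`restock_count` cannot exceed `n_patches`")
  }
  if (cfg$n_dates < 2) stop("`n_dates` must be at least 2")
  for (p in c("predator_trend", "herbivore_trend", "occ_H", "occ_P",
              "col_H", "col_P", "ext_H", "ext_P")) {
    if (cfg[[p]] < 0) stop(sprintf("`%s` must be non-negative", p))
  }
  structure(cfg, class = "pp_synth_config")
}

# numeric ceiling on log(count + 1); only reached by pathological configs
.LOG_CAP <- log(1e12)

# stored as numeric whole numbers: planted couplings can push counts far
# beyond integer range before the ceiling binds
round_count <- function(logx) {
  pmax(0, round(exp(pmin(logx, .LOG_CAP)) - 1))
}

#' Generate an experiment-like synthetic dataset
#'
#' Emulates the structure of a multi-round field experiment on a patch
#' array: daily counts of herbivores and predators on `n_patches` patches
#' over `n_days` days split into `n_rounds` rounds (`run_id` = round). At
#' the start of each round, predators are cleared and re-stocked (one
#' predator on each of `restock_count` random patches); every day,
#' `daily_additions` predators are added to the central patches; within a
#' round, predators are also re-stocked when their total hits the
#' [synth_config()] threshold rule. Each round re-initializes the
#' herbivores as well, so rounds are dynamically independent replicates
#' (the analysis never builds transitions across round boundaries).
#'
#' The update rules plant the ground-truth coefficients: with
#' `P_bar = (P_t + P_{t+1})/2`,
#' \deqn{log(H_{t+1}+1) = log(H_t+1) + log(trend_H) - b_TD P_bar + e_H}
#' \deqn{log(P_{t+1}+1) = log(P_t+1) + log(trend_P) + b_BU H_t + e_P}
#' so the per-interval herbivore decline regressed on mean predator
#' abundance has expected slope `b_TD`, and the predator increase regressed
#' on herbivore abundance has expected slope close to `b_BU` (attenuated
#' slightly by integer rounding and the use of `H_t` rather than the mean).
#' Counts are rounded to non-negative integers after each update.
#'
#' @param cfg a [synth_config()]
#' @return a `pp_ts` with `run_id` = round (1..n_rounds), `time` = absolute
#'   study day (1..n_days)
#' @export
generate_experiment_like <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "pp_synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_patches
  centre <- unique(pmax(1L, c(n %/% 2L, n %/% 2L + 1L)))
  # even split of the study days over rounds (first rounds get the extra day)
  len <- rep(cfg$n_days %/% cfg$n_rounds, cfg$n_rounds)
  extra <- cfg$n_days %% cfg$n_rounds
  if (extra > 0) len[seq_len(extra)] <- len[seq_len(extra)] + 1L

  restock <- function(P) {
    P[] <- 0L
    pick <- sample.int(n, cfg$restock_count)
    P[pick] <- 1L
    P
  }
  add_daily <- function(P) {
    if (cfg$daily_additions > 0) {
      each <- diff(round(seq(0, cfg$daily_additions,
                             length.out = length(centre) + 1L)))
      P[centre] <- P[centre] + as.integer(each)
    }
    P
  }

  out <- vector("list", cfg$n_days)
  day <- 0L
  for (rd in seq_len(cfg$n_rounds)) {
    H <- as.integer(pmax(0, round(stats::rlnorm(n, log(cfg$H_init_mean),
                                                0.5))))
    P <- add_daily(restock(integer(n)))
    low_yesterday <- FALSE
    for (d in seq_len(len[rd])) {
      day <- day + 1L
      if (d > 1L) {
        logP1 <- log(P + 1) + log(cfg$predator_trend) + cfg$b_BU * H +
          stats::rnorm(n, 0, cfg$noise_sd)
        P1 <- add_daily(round_count(logP1))
        tot <- sum(P1)
        if (tot == 0 ||
            (tot <= cfg$restock_total_threshold && low_yesterday)) {
          P1 <- add_daily(restock(P1))
          low_yesterday <- FALSE
        } else {
          low_yesterday <- tot <= cfg$restock_total_threshold
        }
        x_bar <- (P + P1) / 2
        logH1 <- log(H + 1) + log(cfg$herbivore_trend) - cfg$b_TD * x_bar +
          stats::rnorm(n, 0, cfg$noise_sd)
        H <- round_count(logH1)
        P <- P1
      }
      out[[day]] <- data.frame(run_id = rd, patch_id = 0:(n - 1L),
                               time = day, H = H, P = P)
    }
  }
  pp_ts(do.call(rbind, out))
}

#' Generate a field-survey-like synthetic dataset
#'
#' Emulates an observational survey: `n_patches` patches sampled every
#' `interval_days` days for `n_dates` dates. Each species follows an
#' independent presence/absence Markov chain per patch (colonization of
#' empty patches, extinction of occupied ones) with abundance
#' `1 + Poisson(lambda)` when present. Default rates make the herbivore a
#' much better occupier and colonizer than the predator.
#'
#' @param cfg a [synth_config()]
#' @return a `pp_ts` with one run and `n_dates` sampling dates
#' @export
generate_field_like <- function(cfg = synth_config(n_patches = 38L)) {
  stopifnot(inherits(cfg, "pp_synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_patches
  sample_species <- function(occ, col, ext, lambda) {
    pres <- matrix(FALSE, n, cfg$n_dates)
    pres[, 1L] <- stats::runif(n) < occ
    for (d in 2:cfg$n_dates) {
      was <- pres[, d - 1L]
      pres[, d] <- ifelse(was, stats::runif(n) >= ext,
                          stats::runif(n) < col)
    }
    counts <- matrix(0L, n, cfg$n_dates)
    npres <- sum(pres)
    counts[pres] <- 1L + stats::rpois(npres, lambda)
    counts
  }
  Hc <- sample_species(cfg$occ_H, cfg$col_H, cfg$ext_H, cfg$lambda_H)
  Pc <- sample_species(cfg$occ_P, cfg$col_P, cfg$ext_P, cfg$lambda_P)
  times <- (seq_len(cfg$n_dates) - 1L) * cfg$interval_days
  pp_ts(data.frame(
    run_id = 1L,
    patch_id = rep(0:(n - 1L), times = cfg$n_dates),
    time = rep(times, each = n),
    H = as.vector(Hc), P = as.vector(Pc)
  ))
}

#' Generate exchangeable no-interaction data
#'
#' Every patch's series is drawn i.i.d. across patches from a common
#' time-varying distribution: `H_{i,t} ~ Poisson(lambda_H * trend_H^t)` and
#' independently `P_{i,t} ~ Poisson(lambda_P_eff * trend_P^t)` (with
#' `lambda_P_eff = 10 * lambda_P` so predators are reliably present).
#' There is no cross-species coupling and no within-patch persistence, so
#' any within-patch association is zero in expectation: the regime in
#' which the cell-resampling bootstrap null is exact. Used for calibration
#' studies of the null model.
#'
#' @param cfg a [synth_config()]; uses `n_patches`, `n_days`, `lambda_H`,
#'   `lambda_P`, `herbivore_trend`, `predator_trend`, `seed`
#' @return a single-run `pp_ts` with `n_days` daily samples
#' @export
generate_exchangeable_null <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "pp_synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_patches
  tt <- seq_len(cfg$n_days)
  mu_H <- cfg$lambda_H * cfg$herbivore_trend^tt
  mu_P <- 10 * cfg$lambda_P * cfg$predator_trend^tt
  pp_ts(data.frame(
    run_id = 1L,
    patch_id = rep(0:(n - 1L), times = cfg$n_days),
    time = rep(tt, each = n),
    H = stats::rpois(n * cfg$n_days, rep(mu_H, each = n)),
    P = stats::rpois(n * cfg$n_days, rep(mu_P, each = n))
  ))
}
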