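#' Aggregate a patch time series to a larger spatial scale
#'
#' Sums counts over the member patches of each group of the layout's
#' nested hierarchy, producing a time series at group resolution: the
#' "observation at scale s" view of the same data.
#'
#' @param ts a `pp_ts` whose patches match `layout`
#' @param layout a `pp_layout`
#' @param scale group size (power of 3; see [scale_partition()])
#' @return a `pp_ts` whose `patch_id` column holds 0-based group indices
#' @export
aggregate_to_scale <- function(ts, layout, scale) {
  validate_pp_ts(ts)
  m <- ts_matrices(ts)
  if (!identical(as.integer(m$patches), as.integer(layout$patch_ids))) {
    stop("time series patches do not match the layout's patch ids")
  }
  g <- scale_partition(layout, scale)
  Hg <- rowsum(m$H, g, reorder = TRUE)
  Pg <- rowsum(m$P, g, reorder = TRUE)
  matrices_to_ts(list(H = Hg, P = Pg,
                      patches = sort(unique(g)),
                      run = m$run, time = m$time))
}

#' Build the transition table for interaction-strength regressions
#'
#' For every group (or patch) and every pair of consecutive recorded times
#' within the same run/round, computes the log-ratio responses and
#' mean-abundance predictors:
#' \describe{
#'   \item{y_TD}{`log(H_t + 1) - log(H_{t+1} + 1)` — the per-interval
#'     decline of the herbivore (natural log, +1 offsets)}
#'   \item{x_TD}{`(P_t + P_{t+1}) / 2` — mean predator abundance}
#'   \item{y_BU}{`log(P_{t+1} + 1) - log(P_t + 1)` — the per-interval
#'     increase of the predator}
#'   \item{x_BU}{`(H_t + H_{t+1}) / 2` — mean herbivore abundance}
#' }
#' Transitions never span run/round boundaries, and rows in which both
#' species are absent at both ends (`H_t = H_{t+1} = P_t = P_{t+1} = 0`)
#' are removed.
#'
#' @param agg a `pp_ts`, typically from [aggregate_to_scale()]
#' @return a data frame of class `pp_transitions` with columns `group_id`,
#'   `run_id`, `t`, `H_t`, `H_t1`, `P_t`, `P_t1`, `y_TD`, `x_TD`, `y_BU`,
#'   `x_BU`
#' @export
build_transitions <- function(agg) {
  validate_pp_ts(agg)
  m <- ts_matrices(agg)
  j <- transition_cols(m)
  n <- length(m$patches)
  Ht <- m$H[, j, drop = FALSE]
  Ht1 <- m$H[, j + 1L, drop = FALSE]
  Pt <- m$P[, j, drop = FALSE]
  Pt1 <- m$P[, j + 1L, drop = FALSE]
  tt <- data.frame(
    group_id = rep(m$patches, times = length(j)),
    run_id = rep(m$run[j], each = n),
    t = rep(m$time[j], each = n),
    H_t = as.vector(Ht), H_t1 = as.vector(Ht1),
    P_t = as.vector(Pt), P_t1 = as.vector(Pt1)
  )
  keep <- !(tt$H_t == 0 & tt$H_t1 == 0 & tt$P_t == 0 & tt$P_t1 == 0)
  tt <- tt[keep, , drop = FALSE]
  tt$y_TD <- log(tt$H_t + 1) - log(tt$H_t1 + 1)
  tt$x_TD <- (tt$P_t + tt$P_t1) / 2
  tt$y_BU <- log(tt$P_t1 + 1) - log(tt$P_t + 1)
  tt$x_BU <- (tt$H_t + tt$H_t1) / 2
  rownames(tt) <- NULL
  class(tt) <- c("pp_transitions", class(tt))
  tt
}

effect_estimate <- function(y, x, metric) {
  n <- length(y)
  defined <- n >= 3 && stats::var(x) > 0
  if (defined) {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    r <- suppressWarnings(stats::cor(x, y))
  } else {
    slope <- intercept <- r <- NA_real_
  }
  structure(
    list(metric = metric, slope = slope, intercept = intercept,
         n_points = n, pearson_r = r, defined = defined),
    class = "interaction_estimate"
  )
}

#' Top-down interaction strength (effect of predators on prey)
#'
#' Ordinary least-squares regression of the per-interval herbivore decline
#' `y_TD` on mean predator abundance `x_TD`, pooled across all groups and
#' runs in the table. The slope is the per-capita top-down effect (R_TD);
#' the Pearson correlation is reported alongside.
#'
#' @param tt a `pp_transitions` table (one spatial scale)
#' @return an `interaction_estimate`: list with `metric`, `slope`,
#'   `intercept`, `n_points`, `pearson_r`, `defined`. `defined` is `FALSE`
#'   (and the slope `NA`) when there are fewer than 3 points or the
#'   predictor does not vary.
#' @export
top_down_effect <- function(tt) {
  stopifnot(inherits(tt, "pp_transitions"))
  effect_estimate(tt$y_TD, tt$x_TD, "R_TD")
}

#' Bottom-up interaction strength (effect of prey on predators)
#'
#' OLS regression of the per-interval predator increase `y_BU` on mean
#' herbivore abundance `x_BU` (R_BU). See [top_down_effect()].
#'
#' @inheritParams top_down_effect
#' @return an `interaction_estimate`
#' @export
bottom_up_effect <- function(tt) {
  stopifnot(inherits(tt, "pp_transitions"))
  effect_estimate(tt$y_BU, tt$x_BU, "R_BU")
}

#' @export
print.interaction_estimate <- function(x, ...) {
  cat(sprintf("%s: slope = %s (r = %s, n = %d%s)\n", x$metric,
              format(x$slope, digits = 4), format(x$pearson_r, digits = 3),
              x$n_points, if (x$defined) "" else ", undefined"))
  invisible(x)
}

#' Interaction strengths across spatial scales
#'
#' Convenience wrapper: aggregates the patch time series to each requested
#' scale, builds the transition table, and fits both interaction-strength
#' regressions. The largest possible scale (the whole array) is excluded
#' from the default scale list because at that scale a resampling null
#' model is constrained to be nearly identical to the data; pass it
#' explicitly to compute it anyway.
#'
#' @param ts a patch-scale `pp_ts`
#' @param layout a `pp_layout`
#' @param scales integer vector of group sizes (default `c(1, 3, 9, 27)`
#'   for an 81-patch layout: all levels except the full array)
#' @return data frame with one row per (scale, metric): columns `scale`,
#'   `metric`, `slope`, `intercept`, `n_points`, `pearson_r`, `defined`
#' @export
interaction_estimates <- function(ts, layout, scales = default_scales(layout)) {
  rows <- lapply(scales, function(s) {
    tt <- build_transitions(aggregate_to_scale(ts, layout, s))
    do.call(rbind, lapply(list(top_down_effect(tt), bottom_up_effect(tt)),
                          function(e) {
      data.frame(scale = s, metric = e$metric, slope = e$slope,
                 intercept = e$intercept, n_points = e$n_points,
                 pearson_r = e$pearson_r, defined = e$defined)
    }))
  })
  do.call(rbind, rows)
}

#' Default analysis scales for a layout
#'
#' All group sizes of the hierarchy except the whole-array scale.
#'
#' @param layout a `pp_layout`
#' @return integer vector of scales
#' @export
default_scales <- function(layout) {
  if (layout$levels == 0L) return(1L)
  3L^(0:(layout$levels - 1L))
}

#' Patch occupancy of one species
#'
#' Fraction of patches occupied (count > 0) at each sampling date, with the
#' mean and standard error taken across dates.
#'
#' @param ts a `pp_ts` (each `(run_id, time)` combination is one date)
#' @param species `"H"` or `"P"`
#' @return list with `species`, `occupancy_mean`, `occupancy_se`, and the
#'   per-date fractions `by_date`
#' @export
occupancy <- function(ts, species = c("H", "P")) {
  species <- match.arg(species)
  validate_pp_ts(ts)
  if (nrow(ts) == 0L) stop("empty time series")
  date <- interaction(ts$run_id, ts$time, drop = TRUE)
  frac <- tapply(ts[[species]] > 0, date, mean)
  frac <- as.numeric(frac)
  se <- if (length(frac) > 1L) stats::sd(frac) / sqrt(length(frac)) else 0
  list(species = species, occupancy_mean = mean(frac), occupancy_se = se,
       by_date = frac)
}

#' Colonization rate of one species
#'
#' For each interval between consecutive sampling dates (within a run), the
#' colonization rate is the number of patches that were empty at the start
#' and occupied at the end, divided by the number of empty patches at the
#' start. Intervals with no empty patches are skipped; the mean and
#' standard error are taken over the remaining intervals.
#'
#' @inheritParams occupancy
#' @return list with `species`, `colonization_mean`, `colonization_se`,
#'   per-interval rates `by_interval`, and `defined` (`FALSE` when every
#'   interval was skipped)
#' @export
colonization_rate <- function(ts, species = c("H", "P")) {
  species <- match.arg(species)
  validate_pp_ts(ts)
  m <- ts_matrices(ts)
  X <- if (species == "H") m$H else m$P
  j <- transition_cols(m)
  if (length(j) == 0L) stop("need at least 2 sampling dates")
  rates <- vapply(j, function(jj) {
    empty <- X[, jj] == 0
    if (!any(empty)) return(NA_real_)
    sum(empty & X[, jj + 1L] > 0) / sum(empty)
  }, numeric(1))
  rates <- rates[!is.na(rates)]
  if (length(rates) == 0L) {
    return(list(species = species, colonization_mean = NA_real_,
                colonization_se = NA_real_, by_interval = numeric(0),
                defined = FALSE))
  }
  se <- if (length(rates) > 1L) stats::sd(rates) / sqrt(length(rates)) else 0
  list(species = species, colonization_mean = mean(rates),
       colonization_se = se, by_interval = rates, defined = TRUE)
}
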