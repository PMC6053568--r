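#' Simulation parameters
#'
#' Collects all demographic and dispersal parameters of the patch model,
#' plus the run schedule. Local prey (herbivore) dynamics are logistic
#' growth minus type II predation minus background mortality; predator
#' dynamics (when enabled) are assimilation-driven births minus background
#' mortality. Dispersal is density-dependent emigration with logistic
#' smoothing around a threshold, and distance-decaying (incidence-function)
#' settlement that is indiscriminate with respect to the destination state.
#'
#' The default parameter values are the package's documented reference
#' configuration for a desk-scale aphid-ladybeetle-like system; all of them
#' are tunable.
#'
#' @param g_H herbivore intrinsic growth rate (per day)
#' @param k_H herbivore carrying capacity (individuals per patch)
#' @param e_P maximum per-predator predation rate (prey per predator per day)
#' @param H_0 half-saturation prey abundance of the type II functional
#'   response (individuals)
#' @param a_P predator assimilation rate (predator births per prey consumed);
#'   only used in scenario `"with_predator_demography"`
#' @param m_H herbivore background per-capita mortality (per day)
#' @param m_P predator background per-capita mortality (per day); only used
#'   in scenario `"with_predator_demography"`
#' @param d_H_max maximum herbivore per-capita emigration rate (per day)
#' @param tau_H herbivore crowding threshold (individuals): emigration is at
#'   half its maximum when local prey abundance equals `tau_H` and increases
#'   with crowding
#' @param s_H steepness of the herbivore emigration logistic (per individual)
#' @param d_P_max maximum predator per-capita emigration rate (per day)
#' @param tau_P predator prey-scarcity threshold (individuals): emigration is
#'   at half its maximum at `tau_P` and *decreases* with local prey abundance
#'   (the area-restricted-search surrogate: predators linger where prey are
#'   abundant)
#' @param s_P steepness of the predator emigration logistic (per individual)
#' @param alpha settlement-kernel decay (per metre); emigrants settle on
#'   patch j with weight `exp(-alpha * d_ij)`
#' @param w_out external-sink weight (dimensionless, >= 0); with `w_out > 0`
#'   dispersers may leave the system entirely (open-system variant), with
#'   `w_out = 0` the system is closed
#' @param scenario `"no_predator_demography"` (predators only move; their
#'   total is conserved in a closed system) or `"with_predator_demography"`
#'   (predators also reproduce and die)
#' @param t_end simulated time span (days)
#' @param record_times times (days) at which the state is recorded; default
#'   the last 10 days of a 100-day run
#' @param n_runs ensemble size
#' @param H_init_max,P_init_max initial abundances per patch are drawn
#'   uniformly on `0:H_init_max` and `0:P_init_max`
#' @param pop_cap hard cap on total abundance; a run exceeding it aborts
#'   with an error (guards against parameter pathologies)
#' @return an object of class `pp_params` (a named list)
#' @export
sim_params <- function(g_H = 0.3,
                       k_H = 100,
                       e_P = 20,
                       H_0 = 50,
                       a_P = 0.02,
                       m_H = 0.05,
                       m_P = 0.1,
                       d_H_max = 0.3,
                       tau_H = 80,
                       s_H = 0.1,
                       d_P_max = 2,
                       tau_P = 20,
                       s_P = 0.5,
                       alpha = 0.5,
                       w_out = 0,
                       scenario = c("no_predator_demography",
                                    "with_predator_demography"),
                       t_end = 100,
                       record_times = 91:100,
                       n_runs = 300,
                       H_init_max = 20,
                       P_init_max = 1,
                       pop_cap = 1e6) {
  scenario <- match.arg(scenario)
  p <- list(
    g_H = g_H, k_H = k_H, e_P = e_P, H_0 = H_0, a_P = a_P,
    m_H = m_H, m_P = m_P,
    d_H_max = d_H_max, tau_H = tau_H, s_H = s_H,
    d_P_max = d_P_max, tau_P = tau_P, s_P = s_P,
    alpha = alpha, w_out = w_out, scenario = scenario,
    t_end = t_end, record_times = as.numeric(record_times),
    n_runs = as.integer(n_runs),
    H_init_max = as.integer(H_init_max),
    P_init_max = as.integer(P_init_max),
    pop_cap = pop_cap
  )
  validate_params(p)
  structure(p, class = "pp_params")
}

validate_params <- function(p) {
  nonneg <- c("g_H", "e_P", "a_P", "m_H", "m_P", "d_H_max", "s_H",
              "d_P_max", "s_P", "alpha", "w_out", "tau_H", "tau_P")
  for (nm in nonneg) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop(sprintf("parameter `%s` must be finite and non-negative", nm))
    }
  }
  if (p$k_H <= 0) stop("`k_H` must be positive")
  if (p$H_0 <= 0) stop("`H_0` must be positive")
  if (any(p$record_times < 0 | p$record_times > p$t_end)) {
    stop("`record_times` must lie within [0, t_end]")
  }
  invisible(p)
}

#' @export
print.pp_params <- function(x, ...) {
  cat("pp_params:", x$scenario, "\n")
  flds <- setdiff(names(x), c("scenario", "record_times"))
  cat(paste(sprintf("  %s = %s", flds, vapply(x[flds], format, "")),
            collapse = "\n"), "\n")
  cat(sprintf("  record_times = %s..%s (%d)\n", min(x$record_times),
              max(x$record_times), length(x$record_times)))
  invisible(x)
}

#' Type II functional response
#'
#' Per-predator consumption rate `e_P * H / (H + H_0)`: saturating in prey
#' abundance with half-saturation at `H_0`.
#'
#' @param H prey abundance (non-negative; vectorised)
#' @param params a [sim_params()] object
#' @return prey consumed per predator per day
#' @export
functional_response <- function(H, params) {
  if (any(H < 0)) stop("prey abundance must be non-negative")
  params$e_P * H / (H + params$H_0)
}

#' Herbivore per-capita emigration rate
#'
#' Logistic in local prey abundance, increasing with crowding:
#' `d_H_max / (1 + exp(-s_H * (H - tau_H)))`.
#'
#' @inheritParams functional_response
#' @return per-capita emigration rate (per day); vectorised over `H`
#' @export
herbivore_emigration_rate <- function(H, params) {
  if (any(H < 0)) stop("prey abundance must be non-negative")
  params$d_H_max / (1 + exp(-params$s_H * (H - params$tau_H)))
}

#' Predator per-capita emigration rate
#'
#' Logistic in local prey abundance, decreasing as prey become abundant
#' (predators linger on rich patches and leave scarce ones):
#' `d_P_max / (1 + exp(+s_P * (H - tau_P)))`.
#'
#' @inheritParams functional_response
#' @return per-capita emigration rate (per day); vectorised over `H`
#' @export
predator_emigration_rate <- function(H, params) {
  if (any(H < 0)) stop("prey abundance must be non-negative")
  params$d_P_max / (1 + exp(params$s_P * (H - params$tau_P)))
}

#' Local demographic event rates for one patch
#'
#' Returns the Poisson rates of all demographic events at state `(H, P)`.
#' The logistic prey term is split into a birth process (`g_H * H`) and a
#' crowding-death process (`g_H * H^2 / k_H`) so that every rate is
#' non-negative even when `H > k_H`; their difference is the usual logistic
#' net growth. Predator births and background deaths are zero in scenario
#' `"no_predator_demography"`.
#'
#' @param H,P non-negative integer abundances
#' @param params a [sim_params()] object
#' @return named numeric vector of event rates (events per day):
#'   `herbivore_birth`, `herbivore_crowding_death`,
#'   `herbivore_background_death`, `predation`, `predator_birth`,
#'   `predator_background_death`, `herbivore_emigration`,
#'   `predator_emigration`
#' @export
local_event_rates <- function(H, P, params) {
  if (H < 0 || P < 0) stop("abundances must be non-negative")
  fr <- functional_response(H, params)
  demog <- params$scenario == "with_predator_demography"
  c(
    herbivore_birth = params$g_H * H,
    herbivore_crowding_death = params$g_H * H^2 / params$k_H,
    herbivore_background_death = params$m_H * H,
    predation = fr * P,
    predator_birth = if (demog) params$a_P * fr * P else 0,
    predator_background_death = if (demog) params$m_P * P else 0,
    herbivore_emigration = herbivore_emigration_rate(H, params) * H,
    predator_emigration = predator_emigration_rate(H, params) * P
  )
}

#' Expected one-day change of the local dynamics
#'
#' Sums the demographic rate contributions over one day (dispersal off),
#' recovering the mean-field difference equations: the deterministic
#' skeleton of the stochastic model.
#'
#' @inheritParams local_event_rates
#' @return named vector `c(dH = ..., dP = ...)`
#' @export
mean_field_step <- function(H, P, params) {
  r <- local_event_rates(H, P, params)
  c(
    dH = unname(r["herbivore_birth"] - r["herbivore_crowding_death"] -
                  r["predation"] - r["herbivore_background_death"]),
    dP = unname(r["predator_birth"] - r["predator_background_death"])
  )
}

#' Settlement distribution of an emigrant
#'
#' The probability that an emigrant leaving patch `source` settles on patch
#' j is proportional to the incidence-function weight
#' `exp(-alpha * d_source,j)` (zero for the source itself); with
#' `w_out > 0` an additional "outside" destination receives weight `w_out`
#' and the emigrant leaves the system. Settlement is indiscriminate: it does
#' not depend on the species, or on the occupancy of the destination.
#'
#' @param layout a `pp_layout`
#' @param source 0-based patch id of the emigrant's origin
#' @param params a [sim_params()] object (`alpha`, `w_out`)
#' @return numeric vector of length `n_patches + 1`: settlement
#'   probabilities for each patch (in id order) with the final element the
#'   probability of leaving the system; sums to 1
#' @export
settlement_distribution <- function(layout, source, params) {
  stopifnot(inherits(layout, "pp_layout"))
  n <- n_patches(layout)
  if (length(source) != 1L || is.na(source) || source < 0 || source >= n) {
    stop("`source` must be a valid 0-based patch id")
  }
  w <- exp(-params$alpha * layout$dist[source + 1L, ])
  w[source + 1L] <- 0
  w <- c(w, params$w_out)
  tot <- sum(w)
  if (tot <= 0) {
    stop("all settlement weights are zero: no destination available")
  }
  stats::setNames(w / tot, c(layout$patch_ids, "outside"))
}

# settlement matrix for the whole layout: rows = sources, columns =
# patches plus the outside sink; rows sum to 1
settlement_matrix <- function(layout, params) {
  n <- n_patches(layout)
  W <- exp(-params$alpha * layout$dist)
  diag(W) <- 0
  W <- cbind(W, rep(params$w_out, n))
  tot <- rowSums(W)
  if (any(tot <= 0)) {
    stop("all settlement weights are zero for at least one source patch")
  }
  W / tot
}
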