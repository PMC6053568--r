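#' One bootstrap resample of a patch time series
#'
#' The cell-resampling null: for every patch i and every recorded time t
#' (independently, and independently for the two species), the resampled
#' count is the count of a donor patch k drawn uniformly with replacement
#' from all patches at the same time in the same run/round. This destroys
#' within-patch association between the species and across time while
#' preserving, in expectation, every time-specific cross-patch property —
#' in particular shared temporal trends (Moran-type effects, declining
#' predator numbers), which is what makes it a null for *interaction*
#' rather than for trend.
#'
#' `mode = "series"` draws one donor patch per (patch, run) and copies its
#' whole series instead; provided for sensitivity analysis.
#'
#' @param ts a patch-scale `pp_ts` (resampling precedes aggregation)
#' @param mode `"cell"` (default) or `"series"`
#' @return a resampled `pp_ts` of the same shape
#' @export
resample_once <- function(ts, mode = c("cell", "series")) {
  mode <- match.arg(mode)
  validate_pp_ts(ts)
  m <- ts_matrices(ts)
  idx <- resample_indices(m, 1L, mode)
  matrices_to_ts(list(
    H = matrix(m$H[idx$H], nrow = length(m$patches)),
    P = matrix(m$P[idx$P], nrow = length(m$patches)),
    patches = m$patches, run = m$run, time = m$time
  ))
}

# linear indices into an N x C matrix for `b` resampled copies
# (concatenated column-block-wise), independent draws for H and P.
# Draws are made iteration by iteration (H then P) so the RNG stream is
# identical however iterations are batched, and identical to b calls of
# resample_once().
resample_indices <- function(m, b, mode) {
  n <- length(m$patches)
  C <- length(m$time)
  off <- (seq_len(C) - 1L) * n
  one <- if (mode == "cell") {
    function() sample.int(n, n * C, replace = TRUE) + rep(off, each = n)
  } else {
    # one donor per (patch, run) copied across that run's whole series
    runs <- unique(m$run)
    run_col <- match(m$run, runs)
    function() {
      donors <- matrix(sample.int(n, n * length(runs), replace = TRUE),
                       nrow = n)
      as.vector(donors[, run_col, drop = FALSE] + rep(off, each = n))
    }
  }
  H <- vector("list", b)
  P <- vector("list", b)
  for (i in seq_len(b)) {
    H[[i]] <- one()
    P[[i]] <- one()
  }
  list(H = unlist(H), P = unlist(P))
}

# masked per-iteration OLS slopes.
# x, y, mask: (rows x B) matrices; returns length-B slopes, NA if degenerate
masked_slopes <- function(x, y, mask) {
  n <- colSums(mask)
  sx <- colSums(x * mask)
  sy <- colSums(y * mask)
  sxy <- colSums(x * y * mask)
  sxx <- colSums(x * x * mask)
  vxx <- sxx - sx^2 / n
  out <- (sxy - sx * sy / n) / vxx
  out[n < 3 | !is.finite(vxx) | vxx <= 1e-12] <- NA_real_
  out
}

# bootstrap engine: resample at patch scale, aggregate to each requested
# scale, and compute both interaction statistics, for n_iter iterations.
# Returns a list of numeric vectors named "<metric>@<scale>".
null_engine <- function(m, partitions, n_iter, mode, chunk = NULL) {
  n <- length(m$patches)
  C <- length(m$time)
  j <- transition_cols(m)
  J <- length(j)
  if (J == 0L) stop("need at least 2 recorded times per run")
  if (is.null(chunk)) chunk <- max(1L, min(n_iter, floor(4e6 / (n * C))))
  keys <- as.vector(outer(c("R_TD", "R_BU"), names(partitions),
                          paste, sep = "@"))
  out <- lapply(stats::setNames(keys, keys), function(k) numeric(n_iter))
  done <- 0L
  while (done < n_iter) {
    b <- min(chunk, n_iter - done)
    idx <- resample_indices(m, b, mode)
    Hb <- matrix(m$H[idx$H], nrow = n) # N x (C*b)
    Pb <- matrix(m$P[idx$P], nrow = n)
    for (s in names(partitions)) {
      g <- partitions[[s]]
      G <- length(unique(g))
      if (G == n) {
        Hg <- Hb; Pg <- Pb
      } else {
        Hg <- rowsum(Hb, g, reorder = TRUE)
        Pg <- rowsum(Pb, g, reorder = TRUE)
      }
      dim(Hg) <- c(G, C, b)
      dim(Pg) <- c(G, C, b)
      Ht <- Hg[, j, , drop = FALSE]; Ht1 <- Hg[, j + 1L, , drop = FALSE]
      Pt <- Pg[, j, , drop = FALSE]; Pt1 <- Pg[, j + 1L, , drop = FALSE]
      dim(Ht) <- dim(Ht1) <- dim(Pt) <- dim(Pt1) <- c(G * J, b)
      mask <- (Ht + Ht1 + Pt + Pt1) > 0
      y_td <- log(Ht + 1) - log(Ht1 + 1)
      x_td <- (Pt + Pt1) / 2
      y_bu <- log(Pt1 + 1) - log(Pt + 1)
      x_bu <- (Ht + Ht1) / 2
      sl <- done + seq_len(b)
      out[[paste0("R_TD@", s)]][sl] <- masked_slopes(x_td, y_td, mask)
      out[[paste0("R_BU@", s)]][sl] <- masked_slopes(x_bu, y_bu, mask)
    }
    done <- done + b
  }
  out
}

#' Two-tailed bootstrap p-value
#'
#' Mid-rank formula: with B null samples, the rank fraction r is the count
#' of null samples at or below the observed value, plus one half, divided
#' by B + 1; the two-tailed p-value is `2 * min(r, 1 - r)`, clipped to at
#' most 1. The attainable floor is `1 / (B + 1)`.
#'
#' @param samples numeric vector of null statistics (`NA`s are dropped)
#' @param observed observed statistic
#' @return p-value in (0, 1]
#' @export
pvalue_two_sided <- function(samples, observed) {
  samples <- samples[!is.na(samples)]
  B <- length(samples)
  if (B < 100) stop("need at least 100 null samples for a p-value")
  r <- (sum(samples <= observed) + 0.5) / (B + 1)
  min(1, 2 * min(r, 1 - r))
}

#' Bootstrap null distribution of an interaction statistic
#'
#' Repeats [resample_once()] `n_iter` times; each resample is aggregated to
#' the requested scale, the transition table rebuilt, and the interaction
#' statistic recomputed. Summaries are the null median, the percentile 95%
#' interval, and the two-tailed p-value of the observed (unresampled)
#' statistic. Resampling happens at patch scale and is then aggregated, so
#' the same iteration scheme yields consistent nulls across scales (see
#' [null_summary()] to compute several scales from shared resamples).
#'
#' @param ts a patch-scale `pp_ts`
#' @param layout a `pp_layout`
#' @param scale spatial scale (group size)
#' @param metric `"R_TD"` or `"R_BU"`
#' @param n_iter number of bootstrap iterations (>= 100; default 10000)
#' @param seed optional integer seed
#' @param mode resampling mode, see [resample_once()]
#' @return an object of class `pp_null`: list with `scale`, `metric`,
#'   `n_iter`, `seed`, `samples`, `median`, `ci_low`, `ci_high`, `p_value`,
#'   `observed`, `valid` (`FALSE` if more than half the iterations were
#'   degenerate)
#' @export
null_distribution <- function(ts, layout, scale, metric = c("R_TD", "R_BU"),
                              n_iter = 10000, seed = NULL,
                              mode = c("cell", "series")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (n_iter < 100) stop("`n_iter` must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  m <- ts_matrices(ts)
  part <- list(scale_partition(layout, scale))
  names(part) <- as.character(scale)
  samples <- null_engine(m, part, n_iter, mode)[[
    paste0(metric, "@", scale)]]

  tt <- build_transitions(aggregate_to_scale(ts, layout, scale))
  est <- if (metric == "R_TD") top_down_effect(tt) else bottom_up_effect(tt)

  summarize_null(samples, est$slope, scale, metric, n_iter, seed)
}

summarize_null <- function(samples, observed, scale, metric, n_iter, seed) {
  frac_bad <- mean(is.na(samples))
  valid <- frac_bad <= 0.5 && !is.na(observed)
  if (!valid) {
    warning(sprintf(
      "null distribution for %s at scale %s is degenerate (%.0f%% of iterations undefined)",
      metric, scale, 100 * frac_bad
    ))
  }
  qs <- stats::quantile(samples, c(0.025, 0.5, 0.975), na.rm = TRUE,
                        names = FALSE)
  structure(
    list(
      scale = scale, metric = metric, n_iter = n_iter, seed = seed,
      samples = samples, median = qs[2L], ci_low = qs[1L], ci_high = qs[3L],
      p_value = if (valid) pvalue_two_sided(samples, observed) else NA_real_,
      observed = observed, valid = valid
    ),
    class = "pp_null"
  )
}

#' @export
print.pp_null <- function(x, ...) {
  cat(sprintf(
    "%s at scale %s: observed %.4g vs null median %.4g [%.4g, %.4g], p = %.4g (n_iter = %d)\n",
    x$metric, x$scale, x$observed, x$median, x$ci_low, x$ci_high,
    x$p_value, x$n_iter
  ))
  invisible(x)
}

#' Null-model summary table across scales
#'
#' Computes bootstrap nulls for both interaction statistics at several
#' scales from a *shared* set of patch-scale resamples (one resample per
#' iteration, aggregated to every scale), and returns a tidy summary
#' table.
#'
#' @inheritParams null_distribution
#' @param scales integer vector of scales (default [default_scales()])
#' @param metrics character vector among `"R_TD"`, `"R_BU"`
#' @return data frame with one row per (scale, metric): `scale`, `metric`,
#'   `observed`, `median`, `ci_low`, `ci_high`, `p_value`, `n_iter`,
#'   `valid`; the list of `pp_null` objects is attached as attribute
#'   `"nulls"`
#' @export
null_summary <- function(ts, layout, scales = default_scales(layout),
                         metrics = c("R_TD", "R_BU"), n_iter = 10000,
                         seed = NULL, mode = c("cell", "series")) {
  mode <- match.arg(mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (n_iter < 100) stop("`n_iter` must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  m <- ts_matrices(ts)
  parts <- lapply(scales, function(s) scale_partition(layout, s))
  names(parts) <- as.character(scales)
  eng <- null_engine(m, parts, n_iter, mode)
  obs <- interaction_estimates(ts, layout, scales)

  nulls <- list()
  rows <- list()
  for (s in scales) {
    for (met in metrics) {
      o <- obs$slope[obs$scale == s & obs$metric == met]
      nd <- summarize_null(eng[[paste0(met, "@", s)]], o, s, met,
                           n_iter, seed)
      key <- paste0(met, "@", s)
      nulls[[key]] <- nd
      rows[[key]] <- data.frame(
        scale = s, metric = met, observed = o, median = nd$median,
        ci_low = nd$ci_low, ci_high = nd$ci_high, p_value = nd$p_value,
        n_iter = n_iter, valid = nd$valid
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "nulls") <- nulls
  out
}
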