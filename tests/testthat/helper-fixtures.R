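# shared fixtures: tiny layouts and hand-built time series

tiny_layout <- function(levels = 2L) build_fractal_layout(levels)

# a complete single-run series over `times` for `n` patches with given
# count matrices (patches x times)
ts_from_matrices <- function(H, P, times = seq_len(ncol(H)), run_id = 1L) {
  n <- nrow(H)
  pp_ts(data.frame(
    run_id = run_id,
    patch_id = rep(0:(n - 1L), times = length(times)),
    time = rep(times, each = n),
    H = as.vector(H), P = as.vector(P)
  ))
}

# closed-form OLS slope, the independent oracle for regression estimates
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# parameters that freeze all dynamics except those listed
quiet_params <- function(...) {
  sim_params(g_H = 0, k_H = 100, e_P = 0, H_0 = 50, a_P = 0, m_H = 0,
             m_P = 0, d_H_max = 0, d_P_max = 0, ...)
}
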