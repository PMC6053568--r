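lay9 <- tiny_layout(2)

test_that("runs are reproducible from the seed and distinct across seeds", {
  p <- sim_params(t_end = 15, record_times = 6:15)
  a <- run_gillespie(p, lay9, seed = 11)
  b <- run_gillespie(p, lay9, seed = 11)
  c <- run_gillespie(p, lay9, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, c))
  e1 <- run_ensemble(p, lay9, n_runs = 3, seed = 5)
  e2 <- run_ensemble(p, lay9, n_runs = 3, seed = 5)
  expect_identical(e1, e2)
})

test_that("ensemble output has the full (run, patch, time) grid", {
  p <- sim_params(t_end = 12, record_times = 8:12)
  ts <- run_ensemble(p, lay9, n_runs = 4, seed = 2)
  expect_equal(nrow(ts), 4 * 9 * 5)
  expect_false(any(duplicated(ts[c("run_id", "patch_id", "time")])))
  expect_setequal(unique(ts$run_id), 1:4)
  expect_true(all(ts$H >= 0 & ts$P >= 0))
  # reference schedule defaults: 100 days, last 10 recorded, 300 runs
  pd <- sim_params()
  expect_equal(pd$t_end, 100)
  expect_equal(pd$record_times, 91:100)
  expect_equal(pd$n_runs, 300L)
})

test_that("predator number is conserved without demography in a closed system", {
  p <- sim_params(t_end = 25, record_times = seq(5, 25, by = 5),
                  scenario = "no_predator_demography", w_out = 0,
                  P_init_max = 2)
  ts <- run_ensemble(p, lay9, n_runs = 6, seed = 3)
  totals <- tapply(ts$P, list(ts$run_id, ts$time), sum)
  expect_true(all(apply(totals, 1, function(x) length(unique(x)) == 1)))
})

test_that("the all-zero state is absorbing", {
  p <- sim_params(t_end = 10, record_times = c(2, 10))
  ts <- run_gillespie(p, lay9, seed = 1,
                      init = list(H = integer(9), P = integer(9)))
  expect_true(all(ts$H == 0 & ts$P == 0))
})

test_that("dispersal moves individuals without creating or destroying them", {
  # all demography off; only emigration at a high flat rate
  p <- sim_params(g_H = 0, e_P = 0, m_H = 0, d_H_max = 1, s_H = 0,
                  d_P_max = 1, s_P = 0, w_out = 0,
                  t_end = 20, record_times = c(1, 5, 10, 20))
  ts <- run_gillespie(p, lay9, seed = 4,
                      init = list(H = rep(5L, 9), P = rep(2L, 9)))
  expect_true(all(tapply(ts$H, ts$time, sum) == 45))
  expect_true(all(tapply(ts$P, ts$time, sum) == 18))
  # open system: individuals leave and the outside tally accounts for them
  po <- sim_params(g_H = 0, e_P = 0, m_H = 0, d_H_max = 2, s_H = 0,
                   d_P_max = 0, w_out = 5, t_end = 40,
                   record_times = 40)
  tso <- run_gillespie(po, lay9, seed = 4, log_events = TRUE,
                       init = list(H = rep(5L, 9), P = integer(9)))
  out <- attr(tso, "outside")
  expect_equal(sum(tso$H) + unname(out["H"]), 45)
})

test_that("scheduled interventions apply at their exact times", {
  p <- quiet_params(t_end = 10, record_times = c(4, 6, 10))
  iv <- data.frame(time = c(5, 5, 8), patch_id = c(0, 3, 0),
                   species = c("H", "P", "H"), action = c("set", "add", "add"),
                   amount = c(7, 2, 10))
  ts <- run_gillespie(p, lay9, seed = 1, interventions = iv,
                      init = list(H = integer(9), P = integer(9)))
  h0 <- ts$H[ts$patch_id == 0]
  expect_equal(h0[ts$time[ts$patch_id == 0] == 4], 0)
  expect_equal(h0[ts$time[ts$patch_id == 0] == 6], 7)
  expect_equal(h0[ts$time[ts$patch_id == 0] == 10], 17)
  expect_equal(ts$P[ts$patch_id == 3 & ts$time == 6], 2)
  expect_error(run_gillespie(p, lay9, interventions = data.frame(
    time = 1, patch_id = 99, species = "H", action = "set", amount = 1
  )), "range")
})

test_that("the short-horizon mean change matches the mean-field equations", {
  # many replicates of a one-day step from a fixed interior state
  p <- sim_params(g_H = 0.3, k_H = 100, e_P = 5, H_0 = 50, m_H = 0.05,
                  d_H_max = 0, d_P_max = 0, t_end = 1, record_times = 1,
                  scenario = "with_predator_demography", a_P = 0.1,
                  m_P = 0.1)
  lay1 <- build_fractal_layout(0)
  set.seed(42)
  n_rep <- 400
  dH <- dP <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    ts <- run_gillespie(p, lay1, init = list(H = 60L, P = 4L))
    dH[r] <- ts$H - 60
    dP[r] <- ts$P - 4
  }
  mf <- mean_field_step(60, 4, p)
  # the one-day mean change of the jump process differs from the one-step
  # difference equation by O(dt^2) curvature; allow 3 SE plus a small
  # discretization margin
  expect_lt(abs(mean(dH) - mf[["dH"]]),
            3 * stats::sd(dH) / sqrt(n_rep) + 0.6)
  expect_lt(abs(mean(dP) - mf[["dP"]]),
            3 * stats::sd(dP) / sqrt(n_rep) + 0.1)
})

test_that("instrumented runs expose event counts", {
  p <- sim_params(t_end = 10, record_times = 10)
  ts <- run_gillespie(p, lay9, seed = 9, log_events = TRUE)
  counts <- attr(ts, "event_counts")
  expect_named(counts, c("herbivore_birth", "herbivore_crowding_death",
                         "herbivore_background_death", "predation",
                         "predator_birth", "predator_background_death",
                         "herbivore_emigration", "predator_emigration"))
  expect_equal(estimate_event_rate(ts, "predation"),
               unname(counts["predation"]) / 10)
  ts2 <- run_gillespie(p, lay9, seed = 9)
  expect_error(estimate_event_rate(ts2, "predation"), "log_events")
  # zero predators, zero predation events
  pz <- sim_params(t_end = 20, record_times = 20, P_init_max = 0)
  tz <- run_gillespie(pz, lay9, seed = 1, log_events = TRUE)
  expect_equal(unname(attr(tz, "event_counts")["predation"]), 0)
})
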