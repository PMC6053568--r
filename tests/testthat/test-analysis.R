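lay9 <- tiny_layout(2)

test_that("aggregation sums member patches and conserves totals", {
  set.seed(1)
  H <- matrix(rpois(9 * 4, 5), 9, 4)
  P <- matrix(rpois(9 * 4, 1), 9, 4)
  ts <- ts_from_matrices(H, P)
  # identity at scale 1
  expect_equal(as.data.frame(aggregate_to_scale(ts, lay9, 1)),
               as.data.frame(ts))
  # conservation at every time, every scale
  for (s in c(3, 9)) {
    agg <- aggregate_to_scale(ts, lay9, s)
    expect_equal(tapply(agg$H, agg$time, sum), tapply(ts$H, ts$time, sum))
    expect_equal(tapply(agg$P, agg$time, sum), tapply(ts$P, ts$time, sum))
  }
  # hand-checked group sum
  H2 <- matrix(0L, 9, 2); H2[1:3, 1] <- c(2L, 3L, 0L)
  ts2 <- ts_from_matrices(H2, matrix(1L, 9, 2))
  agg2 <- aggregate_to_scale(ts2, lay9, 3)
  expect_equal(agg2$H[agg2$patch_id == 0 & agg2$time == 1], 5L)
  # mismatched patches are rejected
  bad <- ts; bad$patch_id <- bad$patch_id + 100L
  expect_error(aggregate_to_scale(pp_ts(bad), lay9, 3), "match")
})

test_that("transition tables pair consecutive times and drop all-zero pairs", {
  H <- cbind(c(2L, 1L, 0L), c(0L, 1L, 0L), c(4L, 1L, 0L))
  P <- cbind(c(0L, 2L, 0L), c(0L, 2L, 0L), c(1L, 2L, 0L))
  ts <- pp_ts(data.frame(
    run_id = 1L, patch_id = rep(0:2, 3), time = rep(1:3, each = 3),
    H = as.vector(H), P = as.vector(P)
  ))
  tt <- build_transitions(ts)
  # patch 2 is all-zero in both transitions: 2 pairs x 2 patches remain
  expect_equal(nrow(tt), 4L)
  expect_false(any(tt$group_id == 2))
  # log-ratio formula, natural log, +1 offsets
  row <- tt[tt$group_id == 0 & tt$t == 1, ]
  expect_equal(row$y_TD, log(3) - log(1))
  expect_equal(row$x_TD, 0)
  row2 <- tt[tt$group_id == 0 & tt$t == 2, ]
  expect_equal(row2$y_BU, log(2) - log(1))
  expect_equal(row2$x_TD, 0.5)
  expect_equal(row2$x_BU, 2)

  # full grid with no zeros: G * (T - 1) rows
  set.seed(2)
  ts3 <- ts_from_matrices(matrix(rpois(9 * 5, 10) + 1L, 9, 5),
                          matrix(rpois(9 * 5, 2), 9, 5))
  expect_equal(nrow(build_transitions(ts3)), 9 * 4)

  # transitions never span run/round boundaries
  tsr <- rbind(as.data.frame(ts_from_matrices(H + 1L, P, run_id = 1L)),
               as.data.frame(ts_from_matrices(H + 2L, P, run_id = 2L)))
  ttr <- build_transitions(pp_ts(tsr))
  expect_equal(nrow(ttr), 2 * 3 * 2)
  expect_true(all(table(ttr$run_id) == 6))
})

test_that("interaction estimates equal the closed-form OLS slope", {
  # noiseless planted slope
  x <- rep(seq(0, 4, by = 0.5), 3)
  tt <- data.frame(group_id = 1, run_id = 1, t = 1,
                   H_t = 1, H_t1 = 1, P_t = 1, P_t1 = 1,
                   y_TD = 0.5 * x, x_TD = x, y_BU = -0.25 * x, x_BU = x)
  class(tt) <- c("pp_transitions", class(tt))
  td <- top_down_effect(tt)
  expect_equal(td$slope, 0.5, tolerance = 1e-12)
  expect_equal(td$pearson_r, 1, tolerance = 1e-12)
  bu <- bottom_up_effect(tt)
  expect_equal(bu$slope, -0.25, tolerance = 1e-12)

  # random tables against the independent closed-form oracle
  set.seed(33)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    ttr <- data.frame(y_TD = rnorm(n), x_TD = rnorm(n),
                      y_BU = rnorm(n), x_BU = rpois(n, 4))
    class(ttr) <- c("pp_transitions", class(ttr))
    expect_equal(top_down_effect(ttr)$slope,
                 ols_slope(ttr$x_TD, ttr$y_TD), tolerance = 1e-10)
    expect_equal(bottom_up_effect(ttr)$slope,
                 ols_slope(ttr$x_BU, ttr$y_BU), tolerance = 1e-10)
  }

  # constant response: slope exactly zero
  tt0 <- data.frame(y_TD = rep(0, 10), x_TD = 1:10,
                    y_BU = rep(0, 10), x_BU = 1:10)
  class(tt0) <- c("pp_transitions", class(tt0))
  expect_equal(top_down_effect(tt0)$slope, 0)

  # degenerate estimates are flagged, not thrown
  ttd <- data.frame(y_TD = c(1, 2), x_TD = c(1, 2),
                    y_BU = c(1, 2), x_BU = c(1, 2))
  class(ttd) <- c("pp_transitions", class(ttd))
  expect_false(top_down_effect(ttd)$defined)
  ttv <- data.frame(y_TD = rnorm(10), x_TD = rep(2, 10),
                    y_BU = rnorm(10), x_BU = rep(3, 10))
  class(ttv) <- c("pp_transitions", class(ttv))
  est <- top_down_effect(ttv)
  expect_false(est$defined)
  expect_true(is.na(est$slope))
})

test_that("adding an all-zero pair never changes an estimate", {
  set.seed(4)
  H <- matrix(rpois(9 * 4, 6) + 1L, 9, 4)
  P <- matrix(rpois(9 * 4, 2), 9, 4)
  ts <- ts_from_matrices(H, P)
  base <- interaction_estimates(ts, lay9, scales = 1)
  # append a tenth patch that is always empty -- every pair it contributes
  # is all-zero and must be filtered out
  extra <- data.frame(run_id = 1L, patch_id = 9L, time = 1:4, H = 0L, P = 0L)
  ts_aug <- pp_ts(rbind(as.data.frame(ts), extra))
  tt_aug <- build_transitions(ts_aug)
  expect_equal(top_down_effect(tt_aug)$slope,
               base$slope[base$metric == "R_TD"], tolerance = 1e-12)
  expect_equal(bottom_up_effect(tt_aug)$slope,
               base$slope[base$metric == "R_BU"], tolerance = 1e-12)
})

test_that("occupancy summarises presence fractions over dates", {
  # all patches always occupied
  ts <- ts_from_matrices(matrix(3L, 4, 3), matrix(0L, 4, 3))
  occ <- occupancy(ts, "H")
  expect_equal(occ$occupancy_mean, 1)
  expect_equal(occ$occupancy_se, 0)
  expect_equal(occupancy(ts, "P")$occupancy_mean, 0)
  # two dates with fractions 0.5 and 1.0: mean 0.75, SE = sd/sqrt(2) = 0.25
  H <- cbind(c(1L, 0L, 2L, 0L), c(1L, 1L, 2L, 5L))
  occ2 <- occupancy(ts_from_matrices(H, matrix(0L, 4, 2)), "H")
  expect_equal(occ2$occupancy_mean, 0.75)
  expect_equal(occ2$occupancy_se, 0.25)
})

test_that("colonization rate counts refilled empty patches per interval", {
  # counts (0,0,5) then (2,0,1): one colonization / two empty patches
  H <- cbind(c(0L, 0L, 5L), c(2L, 0L, 1L))
  col <- colonization_rate(ts_from_matrices(H, matrix(0L, 3, 2)), "H")
  expect_equal(col$colonization_mean, 0.5)
  expect_true(col$defined)
  # interval without empty patches is skipped
  H2 <- cbind(c(1L, 2L), c(1L, 0L), c(1L, 3L))
  col2 <- colonization_rate(ts_from_matrices(H2, matrix(0L, 2, 3)), "H")
  expect_equal(col2$by_interval, 1) # only the second interval counts
  # all empty, none colonized: rate 0
  H3 <- cbind(c(0L, 0L), c(0L, 0L))
  expect_equal(colonization_rate(ts_from_matrices(H3, matrix(0L, 2, 2)),
                                 "H")$colonization_mean, 0)
  # no empty patches at all: undefined, flagged
  H4 <- cbind(c(1L, 1L), c(1L, 1L))
  expect_false(colonization_rate(ts_from_matrices(H4, matrix(0L, 2, 2)),
                                 "H")$defined)
})
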