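test_that("zero tilt makes the adjusted and raw friction series identical", {
  tr <- generate_trace(quiet_trace_scenario(tilt = 0, meniscus_depth = 0,
                                            fx_baseline = 0.1))
  fr <- slope_adjust(tr)
  expect_equal(fr$F_Fd_adj_mN, fr$F_Fd_raw_mN, tolerance = 1e-7)
  expect_equal(fr$F_Fs_adj_mN, fr$F_Fs_raw_mN, tolerance = 1e-7)
  expect_equal(fr$slope_at_peak, 0, tolerance = 1e-6)
})

test_that("the rotation preserves the force magnitude at every sample", {
  tr <- generate_trace(trace_scenario(seed = 31))
  hm <- fit_height_profile(tr)
  seg <- segment_phases(tr, hm)
  x <- tr$x_mm
  sliding <- x > x[1]
  theta <- atan(height_slope(hm, x[sliding]))
  fx_c <- tr$fx_mN[sliding] - seg$fx_baseline
  fn <- abs(tr$fz_mN[sliding])
  f_adj <- fx_c * cos(theta) - fn * sin(theta)
  n_adj <- fn * cos(theta) + fx_c * sin(theta)
  expect_equal(f_adj^2 + n_adj^2, fx_c^2 + fn^2, tolerance = 1e-9)
})

test_that("adjusted dynamic friction recovers the true coefficient under tilt", {
  for (tl in c(-0.05, -0.02, 0.02, 0.05)) {
    sc <- quiet_trace_scenario(mu_s = 0.5, mu_d = 0.05, tilt = tl,
                               meniscus_depth = 0)
    fr <- slope_adjust(generate_trace(sc))
    expect_lt(abs(fr$mu_d_adj / 0.05 - 1), 0.01)
    expect_lt(abs(fr$mu_s_adj / 0.5 - 1), 0.01)
  }
})

test_that("recovered dynamic friction is tilt-invariant up to |tilt| = 0.1", {
  mus <- vapply(seq(-0.1, 0.1, by = 0.025), function(tl) {
    sc <- quiet_trace_scenario(mu_s = 0.5, mu_d = 0.05, tilt = tl,
                               meniscus_depth = 0)
    slope_adjust(generate_trace(sc))$mu_d_adj
  }, numeric(1))
  expect_lt(max(abs(mus / 0.05 - 1)), 0.01)
})

test_that("opposite tilts agree after adjustment but differ raw by the slope term", {
  up <- slope_adjust(generate_trace(
    quiet_trace_scenario(mu_d = 0.05, mu_s = 0.5, tilt = 0.02,
                         meniscus_depth = 0, F_N_set = 10)))
  down <- slope_adjust(generate_trace(
    quiet_trace_scenario(mu_d = 0.05, mu_s = 0.5, tilt = -0.02,
                         meniscus_depth = 0, F_N_set = 10)))
  expect_lt(abs(up$F_Fd_adj_mN / down$F_Fd_adj_mN - 1), 0.01)
  expect_equal(up$F_Fd_raw_mN - down$F_Fd_raw_mN, 2 * 0.02 * 10,
               tolerance = 0.02)
})

test_that("the static peak is at least the mean dynamic force when mu_s > mu_d", {
  for (seed in 1:3) {
    sc <- trace_scenario(mu_s = 0.5, mu_d = 0.3, noise_sd_F = 0.05,
                         seed = seed)
    fr <- slope_adjust(generate_trace(sc))
    expect_gte(fr$F_Fs_adj_mN, fr$F_Fd_adj_mN)
  }
})

test_that("zero-slope and slope-adjusted estimates agree on a meniscus surface", {
  sc <- quiet_trace_scenario(mu_d = 0.3, tilt = 0.02, meniscus_depth = 0.05)
  fr <- slope_adjust(generate_trace(sc))
  expect_gt(fr$n_zero_slope, 0)
  mu_zero <- fr$F_Fd_zero_slope_mN / fr$F_N_set_mN
  expect_lt(abs(mu_zero / fr$mu_d_adj - 1), 0.02)
})

test_that("excluding the lateral coupling changes the result only at second order", {
  sc <- quiet_trace_scenario(mu_d = 0.3, tilt = 0.05, meniscus_depth = 0)
  tr <- generate_trace(sc)
  full <- slope_adjust(tr, include_lateral = TRUE)
  first <- slope_adjust(tr, include_lateral = FALSE)
  expect_equal(full$F_Fd_adj_mN, first$F_Fd_adj_mN, tolerance = 1e-9)
  expect_lt(abs(first$mu_d_adj / full$mu_d_adj - 1), 0.05)
  expect_false(isTRUE(all.equal(first$mu_d_adj, full$mu_d_adj,
                                tolerance = 1e-6)))
})

test_that("slopes at or beyond 45 degrees are out of regime", {
  t <- seq(0, 14, by = 0.01)
  x <- pmin(pmax(t - 10, 0), 4)
  tr <- as_tribo_trace(
    tibble::tibble(time_s = t, x_mm = x, h_mm = 1.2 * x,
                   fx_mN = 1, fz_mN = -10),
    F_N_set = 10, v_t = 1)
  expect_error(suppressWarnings(slope_adjust(tr)), "45")
})

test_that("a missing static peak yields missing static fields, not an error", {
  t <- seq(0, 14, by = 0.01)
  x <- pmin(pmax(t - 10, 0), 4)
  tr <- as_tribo_trace(
    tibble::tibble(time_s = t, x_mm = x, h_mm = 0.001 * x,
                   fx_mN = 0, fz_mN = -10),
    F_N_set = 10, v_t = 1)
  suppressWarnings(fr <- slope_adjust(tr))
  expect_true(fr$static_missing)
  expect_true(is.na(fr$F_Fs_adj_mN))
  expect_false(is.na(fr$F_Fd_adj_mN))
})
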