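test_that("motion onset is detected within two samples of the true onset", {
  for (seed in 1:3) {
    tr <- generate_trace(trace_scenario(t_pre = 2, seed = seed))
    seg <- segment_phases(tr)
    expect_lte(abs(seg$onset_index - ground_truth(tr)$onset_index), 2)
  }
})

test_that("the pre-movement baseline estimate matches the configured sensor offset", {
  tr <- generate_trace(trace_scenario(fx_baseline = 0.25, seed = 8))
  seg <- segment_phases(tr)
  expect_equal(seg$fx_baseline, 0.25, tolerance = 0.05)
})

test_that("the static peak lands on the generator's peak sample", {
  tr <- generate_trace(quiet_trace_scenario(seed = 2))
  seg <- segment_phases(tr)
  expect_equal(seg$static_peak_index, ground_truth(tr)$static_peak_index)
  expect_false(seg$static_missing)
})

test_that("a flat lateral-force trace flags the static peak as missing", {
  t <- seq(0, 14, by = 0.01)
  x <- pmin(pmax(t - 10, 0), 4)
  tr <- as_tribo_trace(
    tibble::tibble(time_s = t, x_mm = x, h_mm = 0.01 * x,
                   fx_mN = 0, fz_mN = -10),
    F_N_set = 10, v_t = 1)
  expect_warning(seg <- segment_phases(tr), "static")
  expect_true(seg$static_missing)
  expect_true(is.na(seg$static_peak_index))
})

test_that("a trace without motion is rejected", {
  tr <- as_tribo_trace(
    tibble::tibble(time_s = seq(0, 5, 0.01), x_mm = 0, h_mm = 0,
                   fx_mN = 0, fz_mN = -10),
    F_N_set = 10, v_t = 1)
  expect_error(segment_phases(tr), "[Nn]o motion")
})

test_that("phase windows are ordered and disjoint", {
  tr <- generate_trace(trace_scenario(seed = 13))
  seg <- segment_phases(tr)
  expect_lt(max(seg$pre_window), seg$onset_index)
  expect_gte(seg$static_peak_index, seg$onset_index)
  expect_gt(min(seg$stabilization_window), seg$static_peak_index)
  expect_length(intersect(seg$pre_window, seg$stabilization_window), 0)
})

test_that("the zero-slope window exists for a meniscus and is empty for pure tilt", {
  tr <- generate_trace(quiet_trace_scenario(tilt = 0.02, meniscus_depth = 0.05,
                                            seed = 1))
  seg <- segment_phases(tr)
  expect_gt(length(seg$zero_slope_window), 0)
  x0 <- ground_truth(tr)$zero_slope_x
  xw <- range(tr$x_mm[seg$zero_slope_window])
  expect_gte(x0, xw[1] - 0.05)
  expect_lte(x0, xw[2] + 0.05)

  tr2 <- generate_trace(quiet_trace_scenario(tilt = 0.02, meniscus_depth = 0))
  seg2 <- segment_phases(tr2)
  expect_length(seg2$zero_slope_window, 0)
})
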