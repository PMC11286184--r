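test_that("flat, noise-free sliding gives a constant dynamic friction force", {
  sc <- quiet_trace_scenario(mu_s = 0.05, mu_d = 0.05, tilt = 0,
                             meniscus_depth = 0, F_N_set = 10)
  tr <- generate_trace(sc)
  dyn <- tr$fx_mN[tr$x_mm > 1]  # well past the static transition
  expect_equal(dyn, rep(0.5, length(dyn)), tolerance = 1e-7)
})

test_that("tilted noise-free sliding matches the inclined-plane force balance", {
  sc <- quiet_trace_scenario(mu_s = 0.05, mu_d = 0.05, tilt = 0.02,
                             meniscus_depth = 0, F_N_set = 10)
  tr <- generate_trace(sc)
  sel <- tr$x_mm > 1
  expected <- incline_fx_oracle(0.05, 0.02, 10)
  # exact against the independent oracle, and 0.7 mN to first order
  expect_equal(tr$fx_mN[sel], rep(expected, sum(sel)), tolerance = 1e-9)
  expect_equal(expected, 0.7, tolerance = 2e-3)
})

test_that("slide duration equals slide length over tangential speed", {
  tr <- generate_trace(trace_scenario(v_t = 1, slide_length = 4, seed = 3))
  moving <- which(tr$x_mm > 0)
  duration <- tr$time_s[max(moving)] - tr$time_s[min(moving) - 1]
  expect_equal(duration, 4, tolerance = 1e-9)
})

test_that("trace generation is bit-identical under a fixed seed", {
  a <- generate_trace(trace_scenario(seed = 42))
  b <- generate_trace(trace_scenario(seed = 42))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("servo noise and height noise appear at the configured scale", {
  tr <- generate_trace(trace_scenario(noise_sd_F = 0.05, noise_sd_h = 1e-3,
                                      seed = 5))
  pre <- tr$x_mm == 0
  expect_gt(sd(tr$fz_mN[tr$time_s > 5 & pre]), 0.02)
  expect_lt(sd(tr$fz_mN[tr$time_s > 5 & pre]), 0.15)
  expect_gt(sd(tr$h_mm[pre]), 3e-4)
})

test_that("the combined surface profile has one interior zero-slope point and it is reported", {
  sc <- quiet_trace_scenario(tilt = 0.02, meniscus_depth = 0.05, seed = 1)
  tr <- generate_trace(sc)
  x0 <- ground_truth(tr)$zero_slope_x
  expect_true(is.finite(x0))
  expect_gt(x0, 0)
  expect_lt(x0, sc$slide_length)
  # slope of the noiseless height record changes sign exactly once
  sliding <- tr$x_mm > 0
  sl <- diff(tr$h_mm[sliding]) / diff(tr$x_mm[sliding])
  expect_equal(sum(diff(sign(sl)) != 0), 1)
  # and the sign change brackets the reported position
  xm <- tr$x_mm[sliding]
  k <- which(diff(sign(sl)) != 0)
  expect_gt(x0, xm[k])
  expect_lt(x0, xm[k + 2])
  # a monotone tilt-only profile has no interior zero slope
  tr2 <- generate_trace(quiet_trace_scenario(tilt = 0.02, meniscus_depth = 0))
  expect_true(is.na(ground_truth(tr2)$zero_slope_x))
})

test_that("invalid scenarios are rejected", {
  expect_error(trace_scenario(mu_s = 0.1, mu_d = 0.3), ">=")
  expect_error(trace_scenario(F_N_set = 0), "> 0")
  expect_error(trace_scenario(v_t = -1), "> 0")
  expect_error(trace_scenario(slide_length = Inf), "finite")
})
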