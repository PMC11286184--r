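analyse_pair <- function(pair, layout) {
  nuc <- classify_fates(detect_nuclei(pair$blue, pair$pixel_size, "blue"),
                        detect_nuclei(pair$red, pair$pixel_size, "red"))
  compute_damage(nuc, layout)
}

test_that("an undamaged field gives fractions near (1, 0, 0)", {
  pair <- generate_image_pair(small_image_scenario(p_remove = 0, p_dead = 0,
                                                   density_ref = 500,
                                                   seed = 41))
  dm <- analyse_pair(pair, small_image_layout())
  n_track <- dm$n_healthy_track + dm$n_dead_track
  s3 <- 3 * sqrt(1 / n_track + 1 / dm$n_ref_blue)
  expect_lt(abs(dm$rel_blue - 1), s3)
  expect_lt(abs(dm$rel_removed - 0), s3)
  expect_equal(dm$rel_red, 0, tolerance = 0.02)
})

test_that("the partition identity holds exactly on every result", {
  grid <- tidyr::expand_grid(p_remove = c(0, 0.5, 0.8),
                             p_dead = c(0, 0.5))
  for (i in seq_len(nrow(grid))) {
    pair <- generate_image_pair(small_image_scenario(
      p_remove = grid$p_remove[i], p_dead = grid$p_dead[i], seed = 50 + i))
    dm <- analyse_pair(pair, small_image_layout())
    expect_identical(dm$rel_removed, 1 - dm$rel_blue - dm$rel_red)
  }
})

test_that("a harsh-regime scenario recovers fractions near (0.1, 0.1, 0.8)", {
  pair <- generate_image_pair(small_image_scenario(
    p_remove = 0.8, p_dead = 0.5, density_ref = 600, seed = 43))
  dm <- analyse_pair(pair, small_image_layout())
  expect_lt(abs(dm$rel_blue - 0.10), 0.06)
  expect_lt(abs(dm$rel_red - 0.10), 0.06)
  expect_lt(abs(dm$rel_removed - 0.80), 0.08)
})

test_that("a mild-regime scenario shows dead cells but no removal", {
  pair <- generate_image_pair(small_image_scenario(
    p_remove = 0, p_dead = 0.1, density_ref = 600, seed = 44))
  dm <- analyse_pair(pair, small_image_layout())
  expect_lt(abs(dm$rel_red - 0.10), 0.06)
  expect_lt(abs(dm$rel_removed - 0), 0.08)
})

test_that("the statistic is invariant to image intensity rescaling", {
  pair <- generate_image_pair(small_image_scenario(seed = 45))
  dm1 <- analyse_pair(pair, small_image_layout())
  pair$blue <- 0.5 * pair$blue + 0.3
  pair$red <- 0.7 * pair$red + 0.1
  dm2 <- analyse_pair(pair, small_image_layout())
  expect_equal(dm1$rel_blue, dm2$rel_blue, tolerance = 1e-9)
  expect_equal(dm1$rel_red, dm2$rel_red, tolerance = 1e-9)
})

test_that("an empty reference region is an error, not a zero division", {
  nuc <- classify_fates(
    tibble::tibble(x_um = 750, y_um = 400),  # single nucleus in the track
    tibble::tibble(x_um = numeric(0), y_um = numeric(0)))
  expect_error(compute_damage(nuc, small_image_layout()), "undefined")
})

test_that("invalid layouts are rejected", {
  expect_error(region_layout(400, 250, 1500, 800, ref_offset = 200),
               "overlap")
  expect_error(region_layout(100, 250, 1500, 800, ref_offset = 250),
               "outside")
})
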