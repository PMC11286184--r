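test_that("an undamaged track is indistinguishable and labelled all healthy", {
  pair <- generate_image_pair(small_image_scenario(p_remove = 0, p_dead = 0,
                                                   seed = 11))
  expect_true(all(pair$truth$fate == "healthy"))
  expect_equal(unname(pair$expected["rel_removed"]), 0)
})

test_that("track fates follow the configured removal and death probabilities", {
  pair <- generate_image_pair(small_image_scenario(
    p_remove = 0.8, p_dead = 0.5, density_ref = 800, seed = 12))
  expect_equal(unname(pair$expected),
               c(0.1, 0.1, 0.8), tolerance = 1e-12)
  tr <- pair$truth[pair$truth$in_track, ]
  n <- nrow(tr)
  p_rm <- mean(tr$fate == "removed")
  expect_lt(abs(p_rm - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  retained <- tr[tr$fate != "removed", ]
  p_dead <- mean(retained$fate == "dead")
  expect_lt(abs(p_dead - 0.5), 3 * sqrt(0.25 / nrow(retained)))
})

test_that("fate fractions converge to the probabilities at high density", {
  for (seed in 1:3) {
    pair <- generate_image_pair(small_image_scenario(
      p_remove = 0.5, p_dead = 0.25, density_ref = 2000,
      track_width = 400, seed = seed))
    tr <- pair$truth[pair$truth$in_track, ]
    expect_lt(abs(mean(tr$fate == "removed") - 0.5),
              3 * sqrt(0.25 / nrow(tr)))
  }
})

test_that("zero density yields empty ground truth and a background-only image", {
  pair <- generate_image_pair(small_image_scenario(density_ref = 0, seed = 1))
  expect_equal(nrow(pair$truth), 0)
  expect_lt(max(pair$blue), 0.1)  # background + noise only
})

test_that("image generation is bit-identical under a fixed seed", {
  a <- generate_image_pair(small_image_scenario(seed = 9))
  b <- generate_image_pair(small_image_scenario(seed = 9))
  expect_identical(a$blue, b$blue)
  expect_identical(a$red, b$red)
  expect_identical(a$truth, b$truth)
})

test_that("a track band outside the image is rejected", {
  expect_error(image_scenario(track_center_y = 10, track_width = 100),
               "outside")
})

test_that("hard-core spacing thins close pairs only", {
  pair <- generate_image_pair(small_image_scenario(min_spacing_um = 15,
                                                   density_ref = 300,
                                                   seed = 4))
  d <- as.matrix(dist(cbind(pair$truth$x_um, pair$truth$y_um)))
  diag(d) <- Inf
  expect_gte(min(d), 15)
})
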