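label_pair <- function(pair) {
  classify_fates(detect_nuclei(pair$blue, pair$pixel_size, "blue"),
                 detect_nuclei(pair$red, pair$pixel_size, "red"))
}

test_that("an undamaged field yields zero width with a warning", {
  pair <- generate_image_pair(small_image_scenario(p_remove = 0, p_dead = 0,
                                                   seed = 61))
  expect_warning(tw <- estimate_track_width(label_pair(pair)), "width")
  expect_equal(tw$width_um, 0)
})

test_that("a 78 um track with heavy removal is measured to within one bin", {
  sc <- image_scenario(image_width_px = 1500, image_height_px = 400,
                       pixel_size = 2, density_ref = 600, track_width = 78,
                       p_remove = 0.9, p_dead = 0.5, seed = 62)
  pair <- generate_image_pair(sc)
  tw <- estimate_track_width(label_pair(pair), bin_um = 10,
                             extent_um = c(0, 800))
  expect_lt(abs(tw$width_um - 78), 10)
})

test_that("doubling the track width doubles the estimate", {
  base <- image_scenario(image_width_px = 1500, image_height_px = 400,
                         pixel_size = 2, density_ref = 600, track_width = 78,
                         p_remove = 0.9, p_dead = 0.5, seed = 63)
  wide <- base
  wide$track_width <- 156
  tw1 <- estimate_track_width(label_pair(generate_image_pair(base)),
                              bin_um = 10, extent_um = c(0, 800))
  tw2 <- estimate_track_width(label_pair(generate_image_pair(wide)),
                              bin_um = 10, extent_um = c(0, 800))
  expect_gt(tw2$width_um / tw1$width_um, 1.75)
  expect_lt(tw2$width_um / tw1$width_um, 2.25)
})

test_that("the returned profile localises the track", {
  sc <- image_scenario(image_width_px = 1000, image_height_px = 400,
                       pixel_size = 2, density_ref = 600, track_width = 120,
                       track_center_y = 300, p_remove = 0.9, p_dead = 0.3,
                       seed = 64)
  tw <- estimate_track_width(label_pair(generate_image_pair(sc)),
                             bin_um = 10, extent_um = c(0, 800))
  peak <- tw$profile$offset_um[which.max(tw$profile$damage_smooth)]
  expect_lt(abs(peak - 300), 30)
})
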