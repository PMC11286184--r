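#' Describe a synthetic tribometer slide
#'
#' A trace scenario collects every physical and instrumental parameter needed
#' to simulate one single-direction slide of a spherical probe over a (possibly
#' tilted, meniscus-shaped) sample: friction coefficients, normal-force
#' setpoint, kinematics, surface geometry, stick-slip and noise levels.
#'
#' The defaults emulate the study conditions of a glass sphere sliding once
#' over a fibronectin-coated, cell-bearing dish in a low-load tribometer:
#' tangential speed 1 mm/s, 10 s of loading dwell before motion, normal-force
#' setpoints in the 10-80 mN range, and a cured-polymer surface that combines a
#' small mounting tilt with a shallow meniscus bowl.
#'
#' @param mu_s,mu_d Static and dynamic friction coefficients (dimensionless);
#'   `mu_s >= mu_d >= 0`.
#' @param F_N_set Normal-force setpoint in mN (> 0).
#' @param v_t Tangential stage speed in mm/s.
#' @param tilt Surface slope (mm height per mm travel) from sample
#'   misalignment.
#' @param meniscus_depth Peak height deviation in mm of the bowl-shaped
#'   (even-quartic) meniscus profile over the slide span; 0 disables it.
#' @param slide_length Slide length in mm.
#' @param t_pre Pre-movement loading dwell in s.
#' @param stickslip_amp Fractional sawtooth amplitude on the dynamic friction
#'   coefficient (0 disables stick-slip).
#' @param slip_dist Mean distance in mm between stick-slip release events
#'   (exponentially distributed spacings).
#' @param noise_sd_F Gaussian force-noise standard deviation in mN (applied to
#'   both force channels; the normal channel is additionally servo-filtered).
#' @param noise_sd_h Gaussian height-noise standard deviation in mm.
#' @param fx_baseline Lateral-force sensor offset in mN (the pre-movement
#'   baseline an analysis must subtract).
#' @param F_touch Magnitude in mN of the touch force at which loading starts.
#' @param rate Sampling rate in Hz.
#' @param seed Optional integer RNG seed; fixed seed gives bit-identical
#'   traces.
#'
#' @return An object of class `trace_scenario` (a named list).
#' @seealso [generate_trace()]
#' @examples
#' trace_scenario(mu_s = 0.5, mu_d = 0.3, F_N_set = 10)
#' @export
trace_scenario <- function(mu_s = 0.5,
                           mu_d = 0.3,
                           F_N_set = 10,
                           v_t = 1,
                           tilt = 0.02,
                           meniscus_depth = 0.05,
                           slide_length = 4,
                           t_pre = 10,
                           stickslip_amp = 0.1,
                           slip_dist = 0.2,
                           noise_sd_F = 0.02,
                           noise_sd_h = 5e-4,
                           fx_baseline = 0.05,
                           F_touch = 0.3,
                           rate = 100,
                           seed = NULL) {
  check_number(mu_d, "mu_d", lower = 0)
  check_number(mu_s, "mu_s", lower = mu_d)
  check_number(F_N_set, "F_N_set", lower = 0, strict_lower = TRUE)
  check_number(v_t, "v_t", lower = 0, strict_lower = TRUE)
  check_number(tilt, "tilt")
  check_number(meniscus_depth, "meniscus_depth")
  check_number(slide_length, "slide_length", lower = 0, strict_lower = TRUE)
  check_number(t_pre, "t_pre", lower = 0)
  check_number(stickslip_amp, "stickslip_amp", lower = 0)
  check_number(slip_dist, "slip_dist", lower = 0, strict_lower = TRUE)
  check_number(noise_sd_F, "noise_sd_F", lower = 0)
  check_number(noise_sd_h, "noise_sd_h", lower = 0)
  check_number(fx_baseline, "fx_baseline")
  check_number(F_touch, "F_touch", lower = 0)
  check_number(rate, "rate", lower = 0, strict_lower = TRUE)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(
    list(
      mu_s = mu_s, mu_d = mu_d, F_N_set = F_N_set, v_t = v_t, tilt = tilt,
      meniscus_depth = meniscus_depth, slide_length = slide_length,
      t_pre = t_pre, stickslip_amp = stickslip_amp, slip_dist = slip_dist,
      noise_sd_F = noise_sd_F, noise_sd_h = noise_sd_h,
      fx_baseline = fx_baseline, F_touch = F_touch, rate = rate, seed = seed
    ),
    class = "trace_scenario"
  )
}

#' @export
print.trace_scenario <- function(x, ...) {
  cat("<trace_scenario>\n")
  cat(sprintf("  mu_s = %.3f, mu_d = %.3f, F_N = %g mN, v_t = %g mm/s\n",
              x$mu_s, x$mu_d, x$F_N_set, x$v_t))
  cat(sprintf("  tilt = %g, meniscus depth = %g mm, slide = %g mm @ %g Hz\n",
              x$tilt, x$meniscus_depth, x$slide_length, x$rate))
  invisible(x)
}

#' Describe a synthetic two-channel nuclei micrograph pair
#'
#' An image scenario parameterises a blue (all-nuclei) / red (dead-nuclei)
#' fluorescence image pair of a confluent monolayer crossed by a horizontal
#' slide track. Nuclei are placed by a homogeneous spatial Poisson process;
#' inside the track band each nucleus is removed with probability `p_remove`
#' and, if retained, is dead (red-positive) with probability `p_dead`.
#'
#' @param density_ref Nuclei density outside the track, in nuclei per mm^2.
#'   A confluent endothelial monolayer is on the order of a few hundred
#'   nuclei/mm^2.
#' @param track_center_y Track centreline in um from the image top.
#' @param track_width Full track width in um.
#' @param p_remove Probability that a track nucleus is removed.
#' @param p_dead Probability that a retained track nucleus is dead.
#' @param image_width_px,image_height_px Image size in pixels.
#' @param pixel_size Pixel size in um/px.
#' @param nucleus_sigma Gaussian blob radius (sd) in um used to render nuclei.
#' @param amplitude Mean peak intensity of a rendered nucleus (0-1 scale).
#' @param background Constant background intensity (0-1 scale).
#' @param noise_sd Gaussian pixel-noise standard deviation (0-1 scale).
#' @param min_spacing_um Optional hard-core spacing in um: candidate nuclei
#'   closer than this to an already accepted one are discarded. The default 0
#'   keeps the pure Poisson process.
#' @param seed Optional integer RNG seed.
#'
#' @return An object of class `image_scenario` (a named list).
#' @seealso [generate_image_pair()]
#' @examples
#' image_scenario(p_remove = 0.8, p_dead = 0.5)
#' @export
image_scenario <- function(density_ref = 400,
                           track_center_y = NULL,
                           track_width = 78,
                           p_remove = 0.8,
                           p_dead = 0.5,
                           image_width_px = 750,
                           image_height_px = 400,
                           pixel_size = 2,
                           nucleus_sigma = 4,
                           amplitude = 0.6,
                           background = 0.05,
                           noise_sd = 0.01,
                           min_spacing_um = 0,
                           seed = NULL) {
  check_number(density_ref, "density_ref", lower = 0)
  check_number(track_width, "track_width", lower = 0, strict_lower = TRUE)
  check_number(p_remove, "p_remove", lower = 0, upper = 1)
  check_number(p_dead, "p_dead", lower = 0, upper = 1)
  check_number(image_width_px, "image_width_px", lower = 1)
  check_number(image_height_px, "image_height_px", lower = 1)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(nucleus_sigma, "nucleus_sigma", lower = 0, strict_lower = TRUE)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(background, "background", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(min_spacing_um, "min_spacing_um", lower = 0)
  if (!is.null(seed)) check_number(seed, "seed")
  height_um <- image_height_px * pixel_size
  if (is.null(track_center_y)) track_center_y <- height_um / 2
  check_number(track_center_y, "track_center_y")
  if (track_center_y - track_width / 2 < 0 ||
      track_center_y + track_width / 2 > height_um) {
    abort("Track band extends outside the image; shrink `track_width` or move `track_center_y`.")
  }
  structure(
    list(
      density_ref = density_ref, track_center_y = track_center_y,
      track_width = track_width, p_remove = p_remove, p_dead = p_dead,
      image_width_px = as.integer(image_width_px),
      image_height_px = as.integer(image_height_px),
      pixel_size = pixel_size, nucleus_sigma = nucleus_sigma,
      amplitude = amplitude, background = background, noise_sd = noise_sd,
      min_spacing_um = min_spacing_um, seed = seed
    ),
    class = "image_scenario"
  )
}

#' @export
print.image_scenario <- function(x, ...) {
  cat("<image_scenario>\n")
  cat(sprintf("  %d x %d px @ %g um/px, density %g /mm^2\n",
              x$image_width_px, x$image_height_px, x$pixel_size, x$density_ref))
  cat(sprintf("  track %g um wide @ y = %g um, p_remove = %g, p_dead = %g\n",
              x$track_width, x$track_center_y, x$p_remove, x$p_dead))
  invisible(x)
}
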