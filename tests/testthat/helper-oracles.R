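# Shared helpers: independent closed-form oracles and matching utilities.

# Closed-form quasi-static inclined-plane balance: a probe dragged with
# friction coefficient mu over a surface of slope s while a servo holds the
# vertical force at F_vert. Independent of the package's rotation code.
incline_fx_oracle <- function(mu, slope, F_vert) {
  th <- atan(slope)
  N <- F_vert / (cos(th) - mu * sin(th))
  N * (mu * cos(th) + sin(th))
}

# Greedy nearest-neighbour matching of detections to ground-truth positions
# within `radius` um; returns recall and precision.
match_detections <- function(det_x, det_y, true_x, true_y, radius = 5) {
  n_det <- length(det_x)
  n_true <- length(true_x)
  if (n_det == 0 || n_true == 0) {
    return(list(recall = 0, precision = if (n_det == 0) 1 else 0))
  }
  d2 <- outer(true_x, det_x, `-`)^2 + outer(true_y, det_y, `-`)^2
  used_det <- rep(FALSE, n_det)
  matched <- 0L
  ord <- order(apply(d2, 1, min))
  for (i in ord) {
    cand <- which(!used_det & d2[i, ] <= radius^2)
    if (length(cand) > 0) {
      j <- cand[which.min(d2[i, cand])]
      used_det[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(recall = matched / n_true, precision = matched / n_det)
}

# Quiet scenario: noiseless, stick-slip free trace for exactness checks.
quiet_trace_scenario <- function(...) {
  args <- list(stickslip_amp = 0, noise_sd_F = 0, noise_sd_h = 0,
               fx_baseline = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(trace_scenario, args)
}

# Small image scenario used across damage tests: 1.5 x 0.8 mm at 2 um/px.
small_image_scenario <- function(...) {
  args <- list(image_width_px = 750, image_height_px = 400,
               pixel_size = 2, track_width = 250)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(image_scenario, args)
}

small_image_layout <- function() {
  region_layout(track_center_y = 400, track_width = 250,
                image_width_um = 1500, image_height_um = 800,
                ref_offset = 250, ref_width = 200)
}
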