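#' Slope-adjusted static and dynamic friction for one trace
#'
#' Removes the contribution of surface tilt and meniscus curvature from the
#' measured lateral force. With the local surface angle
#' `theta(x) = atan(dh_p/dx)` from the fitted height profile, the measured
#' force pair is rotated into the surface frame:
#' \deqn{F_{F,adj} = F_x \cos\theta - F_N \sin\theta, \quad
#'       F_{N,adj} = F_N \cos\theta + F_x \sin\theta,}
#' with `F_N = |F_z|` and the pre-movement sensor baseline subtracted from
#' `F_x` before rotation. For a quasi-static sphere-on-incline force balance
#' this rotation recovers the interfacial friction force and the true contact
#' normal load exactly.
#'
#' The static value is taken at the static-peak sample; the dynamic value is
#' the mean over the stabilization window. When the surface has a level
#' section, the uncorrected zero-slope estimate (mean baseline-subtracted
#' `F_x` over the zero-slope window) is reported alongside for comparison.
#'
#' @param trace A [as_tribo_trace()] object.
#' @param height_model Optional [fit_height_profile()] result (fitted when
#'   NULL).
#' @param segmentation Optional [segment_phases()] result (computed when
#'   NULL).
#' @param include_lateral Include the lateral force's contribution to the
#'   adjusted normal load (the full rotation). Set FALSE for the first-order
#'   variant `F_{N,adj} = F_N cos(theta)`.
#' @return A one-row tibble of class `friction_result` with raw and adjusted
#'   static/dynamic friction forces (mN), the adjusted normal loads actually
#'   borne at those instants (mN), derived friction coefficients, the surface
#'   slope at the static peak, and bookkeeping columns.
#' @examples
#' tr <- generate_trace(trace_scenario(tilt = 0.03, noise_sd_F = 0,
#'                                     noise_sd_h = 0, stickslip_amp = 0,
#'                                     seed = 1))
#' slope_adjust(tr)$mu_d_adj
#' @export
slope_adjust <- function(trace, height_model = NULL, segmentation = NULL,
                         include_lateral = TRUE) {
  stopifnot(inherits(trace, "tribo_trace"))
  if (is.null(height_model)) height_model <- fit_height_profile(trace)
  if (is.null(segmentation)) segmentation <- segment_phases(trace, height_model)
  meta <- trace_meta(trace)
  if (meta$F_N_set <= 0) abort("Normal-force setpoint must be > 0.")

  x <- trace$x_mm
  sliding <- x > x[1]
  theta <- rep(0, length(x))
  theta[sliding] <- atan(height_slope(height_model, x[sliding]))
  if (any(abs(theta) >= pi / 4)) {
    abort("Local surface angle reaches 45 degrees or more: slope adjustment out of regime.")
  }

  fx_c <- trace$fx_mN - segmentation$fx_baseline
  F_N <- abs(trace$fz_mN)
  F_adj <- fx_c * cos(theta) - F_N * sin(theta)
  N_adj <- F_N * cos(theta) + if (include_lateral) fx_c * sin(theta) else 0

  w <- segmentation$stabilization_window
  F_Fd_raw <- mean(fx_c[w])
  F_Fd_adj <- mean(F_adj[w])
  F_N_dyn <- mean(N_adj[w])

  zw <- segmentation$zero_slope_window
  F_Fd_zero <- if (length(zw) > 0) mean(fx_c[zw]) else NA_real_

  if (!segmentation$static_missing) {
    pk <- segmentation$static_peak_index
    F_Fs_raw <- fx_c[pk]
    F_Fs_adj <- F_adj[pk]
    F_N_sta <- N_adj[pk]
    slope_pk <- tan(theta[pk])
  } else {
    F_Fs_raw <- F_Fs_adj <- F_N_sta <- slope_pk <- NA_real_
  }

  out <- tibble::tibble(
    F_N_set_mN = meta$F_N_set,
    F_Fs_raw_mN = F_Fs_raw,
    F_Fd_raw_mN = F_Fd_raw,
    F_Fs_adj_mN = F_Fs_adj,
    F_Fd_adj_mN = F_Fd_adj,
    F_N_static_mN = F_N_sta,
    F_N_dynamic_mN = F_N_dyn,
    F_Fd_zero_slope_mN = F_Fd_zero,
    mu_s_raw = F_Fs_raw / meta$F_N_set,
    mu_d_raw = F_Fd_raw / meta$F_N_set,
    mu_s_adj = F_Fs_adj / F_N_sta,
    mu_d_adj = F_Fd_adj / F_N_dyn,
    slope_at_peak = slope_pk,
    static_missing = segmentation$static_missing,
    n_stabilization = length(w),
    n_zero_slope = length(zw),
    height_rms_mm = height_model$rms
  )
  class(out) <- c("friction_result", class(out))
  out
}
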