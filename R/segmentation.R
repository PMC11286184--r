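#' Segment a tribometer trace into its experimental phases
#'
#' Identifies the phases of a single-slide friction experiment: the
#' pre-movement dwell, motion onset, the static-friction peak, the stabilized
#' dynamic-sliding window, and (when the surface profile has a level section)
#' the zero-slope window where raw friction can be read off without
#' correction.
#'
#' Motion onset is the first sample whose stage position departs from its
#' initial value by more than `max(3 * sd, 1 um)` (sd of the pre-movement
#' position). The lateral-force baseline is the median over the pre-movement
#' window. The static peak is the largest baseline deviation within
#' `static_search_mm` of travel after onset; if it does not rise above the
#' pre-movement noise floor it is flagged missing rather than invented. The
#' stabilization window runs from the first post-peak sample whose force is
#' within 10% of the trailing dynamic mean to 95% of the slide length. The
#' zero-slope window is the contiguous run of sliding samples around the
#' minimum of `|dh/dx|`, provided that minimum is below `zero_slope_tol`.
#'
#' @param trace A [as_tribo_trace()] object.
#' @param height_model Optional [fit_height_profile()] result; fitted
#'   on the fly when NULL. Needed for the zero-slope window.
#' @param static_search_mm Travel after onset searched for the static peak.
#' @param zero_slope_tol Slope magnitude (mm/mm) below which the surface
#'   counts as level.
#' @return An object of class `phase_segmentation`.
#' @examples
#' tr <- generate_trace(trace_scenario(seed = 1))
#' seg <- segment_phases(tr)
#' seg$onset_index
#' @export
segment_phases <- function(trace, height_model = NULL,
                           static_search_mm = 0.5, zero_slope_tol = 1e-3) {
  stopifnot(inherits(trace, "tribo_trace"))
  x <- trace$x_mm
  fx <- trace$fx_mN
  n <- length(x)

  # motion onset
  x0 <- x[1]
  still <- which(x == x0)
  pre_guess <- seq_len(max(2L, min(still[length(still)], n - 1L)))
  thr <- max(3 * sd(x[pre_guess]), 1e-3)
  onset <- which(abs(x - x0) > thr)[1]
  if (is.na(onset) || onset < 2L) {
    abort("No motion detected: `x_mm` never leaves its initial value.")
  }
  pre_window <- seq_len(onset - 1L)
  fx_bm <- median(fx[pre_window])
  noise_mad <- mad(fx[pre_window])

  # static peak within a bounded search window after onset
  search <- which(x > x0 & x <= x[onset] + static_search_mm)
  peak_rel <- which.max(abs(fx[search] - fx_bm))
  peak_i <- search[peak_rel]
  peak_height <- abs(fx[peak_i] - fx_bm)
  static_missing <- peak_height <= max(5 * noise_mad, 1e-9)
  if (static_missing) {
    warn("No static-friction peak above the pre-movement noise floor; static values will be missing.")
    peak_i <- NA_integer_
  }

  # stabilization window: post-peak decay gone, end effects excluded
  L <- max(x) - x0
  trail <- which(x - x0 >= 0.5 * L & x - x0 <= 0.95 * L)
  trail_mean <- mean(fx[trail])
  stab_tol <- max(0.1 * abs(trail_mean - fx_bm), 5 * noise_mad, 1e-3)
  first_after <- if (is.na(peak_i)) onset else peak_i + 1L
  cand <- which(seq_len(n) >= first_after & x - x0 <= 0.95 * L &
                  (fx - trail_mean) <= stab_tol)
  cand <- cand[cand > onset]
  if (length(cand) == 0) {
    abort("Could not locate a stabilized dynamic-sliding window.")
  }
  stab_window <- cand[1]:max(which(x - x0 <= 0.95 * L))

  # zero-slope window (needs the height profile)
  zero_window <- integer(0)
  if (is.null(height_model)) {
    height_model <- tryCatch(fit_height_profile(trace), error = function(e) NULL)
  }
  if (!is.null(height_model)) {
    sliding <- which(x > x0)
    sl <- abs(height_slope(height_model, x[sliding]))
    if (min(sl) <= zero_slope_tol) {
      ok <- sl <= zero_slope_tol
      runs <- rle(ok)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      k <- which.min(sl)
      hit <- which(starts <= k & ends >= k & runs$values)
      zero_window <- sliding[starts[hit]:ends[hit]]
    }
  }

  structure(
    list(
      onset_index = onset,
      pre_window = pre_window,
      static_peak_index = peak_i,
      static_missing = static_missing,
      stabilization_window = stab_window,
      zero_slope_window = zero_window,
      fx_baseline = fx_bm,
      noise_mad = noise_mad,
      motion_threshold = thr
    ),
    class = "phase_segmentation"
  )
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat("<phase_segmentation>\n")
  cat(sprintf("  onset at sample %d; baseline F_x,bm = %.4g mN\n",
              x$onset_index, x$fx_baseline))
  if (x$static_missing) {
    cat("  static peak: missing (below noise floor)\n")
  } else {
    cat(sprintf("  static peak at sample %d\n", x$static_peak_index))
  }
  cat(sprintf("  stabilization window: %d samples; zero-slope window: %d samples\n",
              length(x$stabilization_window), length(x$zero_slope_window)))
  invisible(x)
}
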