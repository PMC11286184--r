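#' Construct a tribometer trace
#'
#' A tribometer trace is a tibble with one row per sample and columns
#' `time_s` (strictly increasing), `x_mm` (lateral stage position), `h_mm`
#' (measured probe height), `fx_mN` (lateral force) and `fz_mN` (normal force,
#' negative in compression), plus metadata: the normal-force setpoint and the
#' tangential speed.
#'
#' @param data A data frame with the five trace columns.
#' @param F_N_set Normal-force setpoint in mN.
#' @param v_t Tangential speed in mm/s.
#' @param rate Sampling rate in Hz (optional, inferred from `time_s` if NULL).
#' @param ground_truth Optional list of generator ground-truth annotations.
#' @param scenario Optional [trace_scenario()] the trace was generated from.
#'
#' @return A tibble of class `tribo_trace`.
#' @export
as_tribo_trace <- function(data, F_N_set, v_t, rate = NULL,
                           ground_truth = NULL, scenario = NULL) {
  required <- c("time_s", "x_mm", "h_mm", "fx_mN", "fz_mN")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Trace is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)[required]
  if (nrow(data) < 2L) abort("Trace must contain at least two samples.")
  for (col in required) {
    if (!all(is.finite(data[[col]]))) {
      abort(sprintf("Trace column `%s` contains non-finite values.", col))
    }
  }
  if (any(diff(data$time_s) <= 0)) {
    abort("Trace column `time_s` must be strictly increasing.")
  }
  check_number(F_N_set, "F_N_set", lower = 0, strict_lower = TRUE)
  check_number(v_t, "v_t", lower = 0, strict_lower = TRUE)
  if (is.null(rate)) rate <- 1 / median(diff(data$time_s))
  structure(
    data,
    class = c("tribo_trace", class(tibble::tibble())),
    meta = list(F_N_set = F_N_set, v_t = v_t, rate = rate),
    ground_truth = ground_truth,
    scenario = scenario
  )
}

#' Trace metadata and ground truth accessors
#'
#' `trace_meta()` returns the setpoint/speed/rate metadata of a trace;
#' `ground_truth()` returns the generator's ground-truth annotations (NULL for
#' traces read from disk).
#'
#' @param trace A `tribo_trace`.
#' @return A named list, or NULL.
#' @export
trace_meta <- function(trace) attr(trace, "meta")

#' @rdname trace_meta
#' @export
ground_truth <- function(trace) attr(trace, "ground_truth")

#' @export
print.tribo_trace <- function(x, ...) {
  meta <- trace_meta(x)
  cat(sprintf("<tribo_trace> %d samples, F_N = %g mN, v_t = %g mm/s\n",
              nrow(x), meta$F_N_set, meta$v_t))
  NextMethod()
}
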