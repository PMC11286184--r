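#' Batch friction analysis across slides
#'
#' Runs height fitting, phase segmentation and slope adjustment on every
#' trace of a collection, aggregates per-condition summaries, and fits
#' Amonton's law separately to the adjusted static and dynamic friction
#' forces. Individual slide failures are collected and reported, never
#' silently dropped.
#'
#' @param traces A list of [as_tribo_trace()] objects, or an
#'   [generate_experiment_set()] tibble (its `trace` column is used and force
#'   labels are carried over).
#' @param degree Height-polynomial degree passed to [fit_height_profile()].
#' @param include_lateral Passed to [slope_adjust()].
#' @return An object of class `friction_batch`: a list with `results`
#'   (per-slide tibble), `summary` (per-force mean and SD of the adjusted
#'   friction forces and coefficients), `fits` (list with `static` and
#'   `dynamic` [fit_amontons()] objects, NULL when not fittable) and
#'   `failures` (tibble of slide index + error message).
#' @examples
#' es <- generate_experiment_set(c(10, 20), repeats = 2, images = FALSE, seed = 1)
#' fb <- batch_friction(es)
#' fb$fits$dynamic$mu
#' @export
batch_friction <- function(traces, degree = 5, include_lateral = TRUE) {
  if (inherits(traces, "experiment_set")) {
    trace_list <- traces$trace
    repeat_id <- traces$repeat_id
  } else {
    trace_list <- traces
    repeat_id <- seq_along(trace_list)
  }
  n <- length(trace_list)
  empty_fail <- tibble::tibble(slide = integer(0), message = character(0))
  if (n == 0) {
    return(structure(
      list(results = tibble::tibble(), summary = tibble::tibble(),
           fits = list(static = NULL, dynamic = NULL), failures = empty_fail),
      class = "friction_batch"
    ))
  }

  rows <- vector("list", n)
  fails <- list()
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      hm <- fit_height_profile(trace_list[[i]], degree = degree)
      seg <- segment_phases(trace_list[[i]], hm)
      res <- slope_adjust(trace_list[[i]], hm, seg,
                          include_lateral = include_lateral)
      dplyr::mutate(res, slide = i, repeat_id = repeat_id[i], .before = 1)
    }, error = function(e) {
      fails[[length(fails) + 1L]] <<- tibble::tibble(slide = i,
                                                     message = conditionMessage(e))
      NULL
    })
  }
  failures <- if (length(fails) > 0) dplyr::bind_rows(fails) else empty_fail
  if (nrow(failures) > 0) {
    warn(sprintf("%d of %d slides failed friction analysis; see $failures.",
                 nrow(failures), n))
  }
  results <- dplyr::bind_rows(rows)

  summary <- tibble::tibble()
  fits <- list(static = NULL, dynamic = NULL)
  if (nrow(results) > 0) {
    summary <- results %>%
      group_by(.data$F_N_set_mN) %>%
      summarise(
        n_slides = dplyr::n(),
        F_Fs_adj_mean = mean(.data$F_Fs_adj_mN, na.rm = TRUE),
        F_Fs_adj_sd = sd(.data$F_Fs_adj_mN, na.rm = TRUE),
        F_Fd_adj_mean = mean(.data$F_Fd_adj_mN),
        F_Fd_adj_sd = sd(.data$F_Fd_adj_mN),
        mu_s_adj_mean = mean(.data$mu_s_adj, na.rm = TRUE),
        mu_d_adj_mean = mean(.data$mu_d_adj),
        .groups = "drop"
      )
    sta <- dplyr::filter(results, !.data$static_missing)
    if (nrow(sta) >= 2) {
      fits$static <- fit_amontons(sta, f_n = .data$F_N_static_mN,
                                  f_f = .data$F_Fs_adj_mN)
    }
    if (nrow(results) >= 2) {
      fits$dynamic <- fit_amontons(results, f_n = .data$F_N_dynamic_mN,
                                   f_f = .data$F_Fd_adj_mN)
    }
  }
  structure(
    list(results = results, summary = summary, fits = fits,
         failures = failures),
    class = "friction_batch"
  )
}

#' @export
print.friction_batch <- function(x, ...) {
  cat(sprintf("<friction_batch> %d slides analysed, %d failed\n",
              nrow(x$results), nrow(x$failures)))
  if (!is.null(x$fits$static)) {
    cat(sprintf("  static:  mu_s = %.4g\n", x$fits$static$mu))
  }
  if (!is.null(x$fits$dynamic)) {
    cat(sprintf("  dynamic: mu_d = %.4g\n", x$fits$dynamic$mu))
  }
  invisible(x)
}
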