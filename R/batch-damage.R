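#' Batch damage quantification across image pairs
#'
#' Runs nuclei detection, fate classification and the relative-density damage
#' statistic on every image pair of a collection and summarises per force.
#' Individual failures are collected and reported, never silently dropped.
#'
#' @param images A list of `image_pair` objects, or a
#'   [generate_experiment_set()] tibble (its `images` column and force labels
#'   are used).
#' @param layouts A single [region_layout()] applied to all pairs, a list of
#'   layouts (one per pair), or NULL to derive each from the pair's known
#'   track geometry via [layout_for_pair()].
#' @param force_labels Optional normal-force labels in mN (recycled from the
#'   experiment set when given one).
#' @param match_radius Passed to [classify_fates()].
#' @param detect_args Named list of extra arguments for [detect_nuclei()].
#' @param ... Extra arguments for [layout_for_pair()] when layouts are
#'   derived (e.g. `ref_offset`).
#' @return An object of class `damage_batch`: `results` (per-slide tibble),
#'   `summary` (per-force mean and SD of the three fractions) and `failures`.
#' @examples
#' pairs <- list(generate_image_pair(image_scenario(seed = 1)))
#' bd <- batch_damage(pairs, force_labels = 10)
#' bd$results$rel_removed
#' @export
batch_damage <- function(images, layouts = NULL, force_labels = NULL,
                         match_radius = 7, detect_args = list(), ...) {
  if (inherits(images, "experiment_set")) {
    force_labels <- images$force_mN
    repeat_id <- images$repeat_id
    images <- images$images
  } else {
    repeat_id <- seq_along(images)
  }
  n <- length(images)
  empty_fail <- tibble::tibble(slide = integer(0), message = character(0))
  if (n == 0) {
    return(structure(list(results = tibble::tibble(),
                          summary = tibble::tibble(), failures = empty_fail),
                     class = "damage_batch"))
  }
  if (is.null(force_labels)) force_labels <- rep(NA_real_, n)

  rows <- vector("list", n)
  fails <- list()
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      pair <- images[[i]]
      layout <- if (is.null(layouts)) {
        layout_for_pair(pair, ...)
      } else if (inherits(layouts, "region_layout")) {
        layouts
      } else {
        layouts[[i]]
      }
      blue <- do.call(detect_nuclei, c(list(pair$blue, pair$pixel_size, "blue"),
                                       detect_args))
      red <- do.call(detect_nuclei, c(list(pair$red, pair$pixel_size, "red"),
                                      detect_args))
      nuc <- classify_fates(blue, red, match_radius = match_radius)
      res <- compute_damage(nuc, layout, F_N = force_labels[i])
      dplyr::mutate(res, slide = i, repeat_id = repeat_id[i], .before = 1)
    }, error = function(e) {
      fails[[length(fails) + 1L]] <<- tibble::tibble(slide = i,
                                                     message = conditionMessage(e))
      NULL
    })
  }
  failures <- if (length(fails) > 0) dplyr::bind_rows(fails) else empty_fail
  if (nrow(failures) > 0) {
    warn(sprintf("%d of %d image pairs failed damage analysis; see $failures.",
                 nrow(failures), n))
  }
  results <- dplyr::bind_rows(rows)
  summary <- tibble::tibble()
  if (nrow(results) > 0) {
    summary <- results %>%
      group_by(.data$F_N_mN) %>%
      summarise(
        n_slides = dplyr::n(),
        rel_blue_mean = mean(.data$rel_blue),
        rel_blue_sd = sd(.data$rel_blue),
        rel_red_mean = mean(.data$rel_red),
        rel_red_sd = sd(.data$rel_red),
        rel_removed_mean = mean(.data$rel_removed),
        rel_removed_sd = sd(.data$rel_removed),
        .groups = "drop"
      )
  }
  structure(list(results = results, summary = summary, failures = failures),
            class = "damage_batch")
}

#' @export
print.damage_batch <- function(x, ...) {
  cat(sprintf("<damage_batch> %d image pairs analysed, %d failed\n",
              nrow(x$results), nrow(x$failures)))
  invisible(x)
}
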