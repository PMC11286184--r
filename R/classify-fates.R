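#' Classify nuclei as healthy or dead from a two-channel detection pair
#'
#' Matches red (propidium iodide) detections to blue (Hoechst) detections by
#' mutual nearest neighbours within `match_radius`. Matched blue nuclei are
#' dead; unmatched blue nuclei are healthy; red detections without a blue
#' partner still represent dead nuclei and are counted once. Ties are broken
#' by distance, then by index order, so the labelling is deterministic.
#'
#' @param blue,red [detect_nuclei()] results from the blue and red channels
#'   of the same field of view (same physical frame).
#' @param match_radius Maximum centroid distance in um for a blue/red pair to
#'   be the same nucleus (default 7 um, about one nuclear radius).
#' @return A tibble of class `labeled_nuclei` with columns `x_um`, `y_um`,
#'   `fate` (`"healthy"` or `"dead"`), `source` (`"blue"` or `"red"`) and
#'   `match_dist_um` (NA when unmatched).
#' @examples
#' b <- tibble::tibble(x_um = c(10, 50), y_um = c(10, 10))
#' r <- tibble::tibble(x_um = 11, y_um = 10)
#' classify_fates(b, r)$fate
#' @export
classify_fates <- function(blue, red, match_radius = 7) {
  check_number(match_radius, "match_radius", lower = 0)
  nb <- nrow(blue)
  nr <- nrow(red)
  fate <- rep("healthy", nb)
  match_dist <- rep(NA_real_, nb)
  red_matched <- rep(FALSE, nr)
  if (nb > 0 && nr > 0) {
    d2 <- outer(blue$x_um, red$x_um, `-`)^2 + outer(blue$y_um, red$y_um, `-`)^2
    nn_of_blue <- max.col(-d2, ties.method = "first")
    nn_of_red <- apply(d2, 2, which.min)
    for (j in seq_len(nr)) {
      i <- nn_of_red[j]
      if (nn_of_blue[i] == j && d2[i, j] <= match_radius^2) {
        fate[i] <- "dead"
        match_dist[i] <- sqrt(d2[i, j])
        red_matched[j] <- TRUE
      }
    }
  }
  out <- dplyr::bind_rows(
    tibble::tibble(x_um = blue$x_um, y_um = blue$y_um, fate = fate,
                   source = "blue", match_dist_um = match_dist),
    tibble::tibble(x_um = red$x_um[!red_matched],
                   y_um = red$y_um[!red_matched],
                   fate = "dead", source = "red", match_dist_um = NA_real_)
  )
  class(out) <- c("labeled_nuclei", class(out))
  out
}
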