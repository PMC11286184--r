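#' Define slide-track and reference regions for damage quantification
#'
#' The damage statistic compares nuclei densities inside the slide band with
#' the blue-nucleus density in undisturbed reference areas flanking it. This
#' constructor builds a horizontal track band plus two flanking rectangular
#' reference bands and validates that all regions are disjoint and inside the
#' image.
#'
#' @param track_center_y Track centreline in um.
#' @param track_width Full track width in um.
#' @param image_width_um,image_height_um Image extent in um.
#' @param x_range Along-track extent analysed, in um (default full width).
#' @param ref_offset Distance in um between the track centreline and each
#'   reference-band centreline (default 3x the track width).
#' @param ref_width Reference band width in um (default equal to the track
#'   width).
#' @return An object of class `region_layout` with the track rectangle, the
#'   list of reference rectangles (um, `c(xmin, xmax, ymin, ymax)`), and the
#'   region areas in mm^2.
#' @examples
#' region_layout(400, 78, 1500, 800)
#' @export
region_layout <- function(track_center_y, track_width,
                          image_width_um, image_height_um,
                          x_range = c(0, image_width_um),
                          ref_offset = 3 * track_width,
                          ref_width = track_width) {
  check_number(track_width, "track_width", lower = 0, strict_lower = TRUE)
  check_number(ref_width, "ref_width", lower = 0, strict_lower = TRUE)
  check_number(ref_offset, "ref_offset", lower = 0, strict_lower = TRUE)
  track <- c(x_range[1], x_range[2],
             track_center_y - track_width / 2, track_center_y + track_width / 2)
  refs <- list(
    c(x_range[1], x_range[2],
      track_center_y - ref_offset - ref_width / 2,
      track_center_y - ref_offset + ref_width / 2),
    c(x_range[1], x_range[2],
      track_center_y + ref_offset - ref_width / 2,
      track_center_y + ref_offset + ref_width / 2)
  )
  all_rects <- c(list(track), refs)
  for (r in all_rects) {
    if (r[1] < 0 || r[2] > image_width_um || r[3] < 0 || r[4] > image_height_um) {
      abort("Region extends outside the image; adjust offsets/widths.")
    }
    if (r[2] <= r[1] || r[4] <= r[3]) abort("Degenerate (zero-area) region.")
  }
  if (refs[[1]][4] > track[3] || refs[[2]][3] < track[4]) {
    abort("Reference regions must not overlap the slide band.")
  }
  area_mm2 <- function(r) (r[2] - r[1]) * (r[4] - r[3]) / 1e6
  structure(
    list(track = track, refs = refs,
         A_track_mm2 = area_mm2(track),
         A_ref_mm2 = sum(vapply(refs, area_mm2, numeric(1)))),
    class = "region_layout"
  )
}

#' Default region layout for a generated image pair
#'
#' Builds a [region_layout()] from the known track geometry of a synthetic
#' [generate_image_pair()] result (or a sidecar-described real image).
#'
#' @param pair An `image_pair`.
#' @param ... Overrides passed to [region_layout()] (e.g. `ref_offset`).
#' @return A `region_layout`.
#' @export
layout_for_pair <- function(pair, ...) {
  s <- pair$scenario
  region_layout(
    track_center_y = s$track_center_y,
    track_width = s$track_width,
    image_width_um = nrow(pair$blue) * pair$pixel_size,
    image_height_um = ncol(pair$blue) * pair$pixel_size,
    ...
  )
}

in_rect <- function(x, y, r) x >= r[1] & x <= r[2] & y >= r[3] & y <= r[4]

#' Relative nuclei densities in the slide track versus reference areas
#'
#' Computes the monolayer-damage statistic: the healthy (blue, not
#' red-matched) and dead nuclei densities inside the slide band are divided
#' by the pooled blue-nucleus density over the reference areas, and the
#' removed fraction follows as the complement,
#' `rel_removed = 1 - rel_blue - rel_red`. The removed fraction is reported
#' as-is (it can legitimately be slightly negative when the track happens to
#' be denser than the reference areas), never clipped.
#'
#' @param nuclei A [classify_fates()] result.
#' @param layout A [region_layout()].
#' @param F_N Optional normal-force label in mN carried into the result.
#' @return A one-row tibble of class `damage_result` with relative fractions,
#'   raw counts, densities (nuclei/mm^2) and region areas.
#' @examples
#' pair <- generate_image_pair(image_scenario(p_remove = 0, p_dead = 0, seed = 1))
#' nuc <- classify_fates(detect_nuclei(pair$blue, 2, "blue"),
#'                       detect_nuclei(pair$red, 2, "red"))
#' compute_damage(nuc, layout_for_pair(pair))$rel_removed
#' @export
compute_damage <- function(nuclei, layout, F_N = NA_real_) {
  stopifnot(inherits(layout, "region_layout"))
  blue <- nuclei$source == "blue"
  n_ref_blue <- sum(vapply(
    layout$refs,
    function(r) sum(blue & in_rect(nuclei$x_um, nuclei$y_um, r)),
    numeric(1)))
  if (n_ref_blue == 0) {
    abort("No blue nuclei in the reference regions: reference density (and the statistic) is undefined.")
  }
  rho_ref <- n_ref_blue / layout$A_ref_mm2

  tr <- layout$track
  in_track <- in_rect(nuclei$x_um, nuclei$y_um, tr)
  n_healthy <- sum(in_track & nuclei$fate == "healthy")
  n_dead <- sum(in_track & nuclei$fate == "dead")
  d_healthy <- n_healthy / layout$A_track_mm2
  d_dead <- n_dead / layout$A_track_mm2

  rel_blue <- d_healthy / rho_ref
  rel_red <- d_dead / rho_ref
  out <- tibble::tibble(
    F_N_mN = F_N,
    rel_blue = rel_blue,
    rel_red = rel_red,
    rel_removed = 1 - rel_blue - rel_red,
    n_healthy_track = n_healthy,
    n_dead_track = n_dead,
    n_ref_blue = n_ref_blue,
    density_healthy_track = d_healthy,
    density_dead_track = d_dead,
    density_ref = rho_ref,
    A_track_mm2 = layout$A_track_mm2,
    A_ref_mm2 = layout$A_ref_mm2
  )
  class(out) <- c("damage_result", class(out))
  out
}
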