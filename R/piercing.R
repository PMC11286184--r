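#' Monolayer-piercing model
#'
#' Describes the two-stage contact of a sphere with a cell monolayer on a
#' much stiffer substrate. The monolayer (undeformed thickness `h_cell`) is
#' soft and easily pierced: cells compressed below a critical thickness
#' `h_crit` burst. Once pierced, the substrate bears the load
#' (load-transparent monolayer) and the sphere indents it by the Hertz
#' indentation depth.
#'
#' @param substrate A [material()] for the substrate.
#' @param probe A [sphere_probe()].
#' @param probe_material A [material()] for the probe (default glass).
#' @param h_cell Undeformed monolayer thickness in um.
#' @param h_crit Critical compressed thickness in um at which cells burst;
#'   `0 < h_crit <= h_cell`.
#' @return An object of class `piercing_model`.
#' @examples
#' md <- material_defaults()
#' piercing_model(md$ps, md$probe)
#' @export
piercing_model <- function(substrate, probe,
                           probe_material = material_defaults()$glass,
                           h_cell = 3, h_crit = 0.8) {
  stopifnot(inherits(substrate, "tribo_material"),
            inherits(probe, "sphere_probe"),
            inherits(probe_material, "tribo_material"))
  check_number(h_cell, "h_cell", lower = 0, strict_lower = TRUE)
  check_number(h_crit, "h_crit", lower = 0, upper = h_cell,
               strict_lower = TRUE)
  structure(
    list(substrate = substrate, probe = probe,
         probe_material = probe_material,
         h_cell = h_cell, h_crit = h_crit,
         E_star_kPa = effective_modulus(substrate, probe_material)),
    class = "piercing_model"
  )
}

#' Predicted slide-track width under the piercing model
#'
#' Geometric kill criterion: after piercing, the sphere indents the substrate
#' by the Hertz depth `delta` and the sphere-substrate gap at lateral radius
#' r is `g(r) = r^2 / (2R) - delta`. Cells are destroyed wherever the gap is
#' below the critical thickness, giving the kill half-width
#' `r_kill = sqrt(2 R (h_crit + delta))` and a predicted full track width of
#' `2 r_kill`. Because `delta` is small on a stiff substrate, the width is
#' dominated by the load-independent `sqrt(2 R h_crit)` term - which is why
#' the observed track barely widens while the Hertz contact radius grows as
#' `F^(1/3)`.
#'
#' The load-sharing report states the fraction of the normal load borne by
#' the substrate (1 under the load-transparent assumption) and the radius
#' `r_touch = sqrt(2 R (h_cell + delta))` out to which the sphere touches the
#' (uncompressed) monolayer.
#'
#' @param F Normal force(s) in mN (vectorised).
#' @param model A [piercing_model()].
#' @return A tibble with one row per force: `F_mN`, `a_um` (Hertz contact
#'   radius on the substrate), `delta_um`, `r_kill_um`, `width_um`,
#'   `r_touch_um` and `substrate_load_fraction`.
#' @examples
#' md <- material_defaults()
#' pm <- piercing_model(md$ps, md$probe, h_crit = 0.76)
#' pierced_track_width(c(10, 80), pm)$width_um
#' @export
pierced_track_width <- function(F, model) {
  stopifnot(inherits(model, "piercing_model"))
  hc <- hertz_contact(F, model$probe, model$E_star_kPa)
  R_um <- model$probe$R_mm * 1e3
  r_kill <- sqrt(2 * R_um * (model$h_crit + hc$delta_um))
  r_touch <- sqrt(2 * R_um * (model$h_cell + hc$delta_um))
  tibble::tibble(
    F_mN = hc$F_mN,
    a_um = hc$a_um,
    delta_um = hc$delta_um,
    r_kill_um = r_kill,
    width_um = 2 * r_kill,
    r_touch_um = r_touch,
    substrate_load_fraction = 1
  )
}

#' Critical cell thickness implied by an observed track width
#'
#' Inverts the piercing-model width prediction for `h_crit` given an observed
#' full track width at a reference force: on a rigid substrate this is the
#' closed form `h_crit = (width/2)^2 / (2R)`; with an elastic substrate the
#' Hertz indentation at the reference force is subtracted.
#'
#' @param width_um Observed full track width in um.
#' @param probe A [sphere_probe()].
#' @param F,E_star Optional reference force (mN) and effective modulus (kPa);
#'   when supplied the substrate indentation is accounted for, otherwise the
#'   substrate is treated as rigid.
#' @return Implied `h_crit` in um.
#' @examples
#' implied_h_crit(77.8, sphere_probe(1))
#' @export
implied_h_crit <- function(width_um, probe, F = NULL, E_star = NULL) {
  stopifnot(inherits(probe, "sphere_probe"))
  check_number(width_um, "width_um", lower = 0, strict_lower = TRUE)
  R_um <- probe$R_mm * 1e3
  h <- (width_um / 2)^2 / (2 * R_um)
  if (!is.null(F) && !is.null(E_star)) {
    h <- h - hertz_contact(F, probe, E_star)$delta_um
  }
  h
}

#' @export
print.piercing_model <- function(x, ...) {
  cat(sprintf(
    "<piercing_model> h_cell = %g um, h_crit = %g um, E* = %.4g kPa, R = %g mm\n",
    x$h_cell, x$h_crit, x$E_star_kPa, x$probe$R_mm))
  invisible(x)
}
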