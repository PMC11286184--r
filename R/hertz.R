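#' Material and probe descriptions for contact calculations
#'
#' `material()` describes a linear-elastic solid by Young's modulus (kPa) and
#' Poisson ratio; `sphere_probe()` describes a spherical probe by its radius
#' in mm. `material_defaults()` returns the materials used throughout:
#' soda-lime glass (70 GPa, nu 0.22), polystyrene (3 GPa, nu 0.35) and the
#' soft PDMS substrate (73.32 kPa, nu 0.5, incompressible); the PDMS modulus
#' is the measured value for the gel formulation used, the others are
#' literature-typical values.
#'
#' @param E Young's modulus in kPa (> 0).
#' @param nu Poisson ratio, in (-1, 0.5].
#' @param R Sphere radius in mm (> 0).
#' @return `material()`/`sphere_probe()` return classed lists;
#'   `material_defaults()` a named list of materials plus a 1 mm glass probe.
#' @examples
#' material_defaults()$pdms
#' @export
material <- function(E, nu) {
  check_number(E, "E", lower = 0, strict_lower = TRUE)
  check_number(nu, "nu", lower = -1, upper = 0.5)
  if (nu <= -1) abort("`nu` must be > -1.")
  structure(list(E_kPa = E, nu = nu), class = "tribo_material")
}

#' @rdname material
#' @export
sphere_probe <- function(R) {
  check_number(R, "R", lower = 0, strict_lower = TRUE)
  structure(list(R_mm = R), class = "sphere_probe")
}

#' @rdname material
#' @export
material_defaults <- function() {
  list(
    glass = material(E = 70e6, nu = 0.22),
    ps = material(E = 3.0e6, nu = 0.35),
    pdms = material(E = 73.32, nu = 0.5),
    probe = sphere_probe(R = 1)
  )
}

#' Effective contact modulus of a material pairing
#'
#' Computes the plane-strain effective modulus of Hertz theory,
#' `1/E* = (1 - nu1^2)/E1 + (1 - nu2^2)/E2`.
#'
#' @param m1,m2 [material()] objects.
#' @return Effective modulus E* in kPa.
#' @examples
#' effective_modulus(material(100, 0.5), material(100, 0.5)) # (2/3) * 100
#' @export
effective_modulus <- function(m1, m2) {
  stopifnot(inherits(m1, "tribo_material"), inherits(m2, "tribo_material"))
  1 / ((1 - m1$nu^2) / m1$E_kPa + (1 - m2$nu^2) / m2$E_kPa)
}

#' Hertz sphere-on-half-space contact
#'
#' Closed-form Hertz contact quantities for a rigid-geometry sphere of radius
#' R pressed on an elastic half-space with effective modulus E*: contact
#' radius `a = (3 F R / (4 E*))^(1/3)`, indentation `delta = a^2 / R`, and
#' maximum (centre) pressure `p0 = 3 F / (2 pi a^2)`. Computed in SI
#' internally, reported in the units stated below.
#'
#' @param F Normal force(s) in mN (>= 0; vectorised).
#' @param probe A [sphere_probe()].
#' @param E_star Effective modulus in kPa (see [effective_modulus()]).
#' @return A tibble with one row per force: `F_mN`, `a_um`, `delta_um`,
#'   `p0_kPa`, `E_star_kPa`.
#' @examples
#' md <- material_defaults()
#' hertz_contact(10, md$probe, effective_modulus(md$glass, md$pdms))
#' @export
hertz_contact <- function(F, probe, E_star) {
  stopifnot(inherits(probe, "sphere_probe"))
  if (any(!is.finite(F)) || any(F < 0)) abort("`F` must be finite and >= 0.")
  check_number(E_star, "E_star", lower = 0, strict_lower = TRUE)
  F_N <- F * 1e-3          # N
  R <- probe$R_mm * 1e-3   # m
  Es <- E_star * 1e3       # Pa
  a <- (3 * F_N * R / (4 * Es))^(1 / 3)
  delta <- a^2 / R
  p0 <- ifelse(F_N > 0, 3 * F_N / (2 * pi * a^2), 0)
  tibble::tibble(
    F_mN = F,
    a_um = a * 1e6,
    delta_um = delta * 1e6,
    p0_kPa = p0 / 1e3,
    E_star_kPa = E_star
  )
}

#' Maximum Hertz pressure across forces and material pairings
#'
#' Tabulates the theoretical maximum Hertz pressure p0 between the probe and
#' the bare substrate for each force and pairing, the severity gauge used to
#' put mild (soft-substrate) and harsh (stiff-substrate) load regimes on a
#' common axis.
#'
#' @param forces Normal forces in mN (non-empty).
#' @param pairings A named list of pairings, each a list with elements
#'   `probe` ([sphere_probe()]), `m1` and `m2` ([material()]).
#' @return A tibble with one row per (force, pairing): the pairing label,
#'   force and Hertz quantities.
#' @examples
#' md <- material_defaults()
#' pressure_sweep(c(10, 80), list(
#'   pdms = list(probe = md$probe, m1 = md$glass, m2 = md$pdms)))
#' @export
pressure_sweep <- function(forces, pairings) {
  if (length(forces) == 0) abort("`forces` must be non-empty.")
  if (length(pairings) == 0) abort("`pairings` must be non-empty.")
  labels <- names(pairings) %||% as.character(seq_along(pairings))
  purrr::map2(pairings, labels, function(p, lab) {
    Es <- effective_modulus(p$m1, p$m2)
    dplyr::mutate(hertz_contact(forces, p$probe, Es), pairing = lab,
                  .before = 1)
  }) %>%
    dplyr::bind_rows()
}
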