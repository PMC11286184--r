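# Matched trace + image-pair collections emulating a full study design.

#' Default load-to-damage mapping for simulated experiment sets
#'
#' Maps a normal force in mN to track damage probabilities `p_remove` and
#' `p_dead` (probability that a retained track nucleus is dead). The default
#' emulates the harsh-load regime observed on stiff polystyrene substrates,
#' where the removed fraction climbs from roughly 0.46 at 10 mN to 0.80 at
#' 80 mN while about half of the retained track nuclei are dead; values are
#' interpolated linearly in log2(force) and clamped at the ends.
#'
#' @param F_N Normal force(s) in mN.
#' @return A list with numeric vectors `p_remove` and `p_dead`.
#' @export
damage_map_ps <- function(F_N) {
  anchors_F <- log2(c(10, 20, 40, 80))
  p_remove <- approx(anchors_F, c(0.46, 0.58, 0.76, 0.80),
                     xout = pmin(pmax(log2(F_N), anchors_F[1]), anchors_F[4]))$y
  p_dead <- approx(anchors_F, c(0.48, 0.52, 0.58, 0.50),
                   xout = pmin(pmax(log2(F_N), anchors_F[1]), anchors_F[4]))$y
  list(p_remove = p_remove, p_dead = p_dead)
}

#' Simulate a full friction-and-damage experiment set
#'
#' Generates one tribometer trace and one blue/red image pair per
#' (normal force, repeat) combination, emulating a study design of several
#' slides per load condition. Child RNG seeds are derived deterministically
#' from `seed`, so a fixed seed yields a bit-identical collection.
#'
#' @param forces Normal-force setpoints in mN (all > 0, non-empty).
#' @param repeats Number of repeats per force (>= 0).
#' @param trace_template A [trace_scenario()] whose `F_N_set`, `noise_sd_F`
#'   and `seed` are overridden per slide.
#' @param image_template An [image_scenario()] whose damage probabilities and
#'   `seed` are overridden per slide.
#' @param noise_rel Relative force-noise level: per-sample Gaussian noise with
#'   sd `noise_rel * mu_d * F_N` (i.e. relative to the dynamic friction
#'   signal).
#' @param damage_map Function mapping force in mN to `list(p_remove, p_dead)`;
#'   defaults to [damage_map_ps()].
#' @param images Set FALSE to skip image generation (friction-only sets).
#' @param seed Optional integer seed for the whole collection.
#'
#' @return A tibble of class `experiment_set` with columns `force_mN`,
#'   `repeat_id`, `trace` (list of `tribo_trace`) and `images` (list of
#'   `image_pair` or NULL).
#' @examples
#' es <- generate_experiment_set(c(10, 20), repeats = 1, images = FALSE, seed = 1)
#' nrow(es)
#' @export
generate_experiment_set <- function(forces, repeats = 9,
                                    trace_template = trace_scenario(),
                                    image_template = image_scenario(),
                                    noise_rel = 0.05,
                                    damage_map = damage_map_ps,
                                    images = TRUE,
                                    seed = NULL) {
  if (length(forces) == 0) abort("`forces` must be non-empty.")
  if (any(!is.finite(forces)) || any(forces <= 0)) {
    abort("All `forces` must be finite and > 0.")
  }
  check_number(repeats, "repeats", lower = 0)
  design <- tidyr::expand_grid(force_mN = as.numeric(forces),
                               repeat_id = seq_len(repeats))
  n <- nrow(design)
  seeds <- derive_seeds(seed, 2L * max(n, 1L))
  dmg <- damage_map(design$force_mN)

  traces <- purrr::map(seq_len(n), function(i) {
    sc <- trace_template
    sc$F_N_set <- design$force_mN[i]
    sc$noise_sd_F <- noise_rel * sc$mu_d * sc$F_N_set
    sc$seed <- seeds[[i]]
    generate_trace(sc)
  })
  image_pairs <- purrr::map(seq_len(n), function(i) {
    if (!images) return(NULL)
    sc <- image_template
    sc$p_remove <- dmg$p_remove[i]
    sc$p_dead <- dmg$p_dead[i]
    sc$seed <- seeds[[n + i]]
    generate_image_pair(sc)
  })
  out <- design
  out$trace <- traces
  out$images <- image_pairs
  structure(out, class = c("experiment_set", class(tibble::tibble())))
}
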