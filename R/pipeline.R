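#' Build a pipeline run configuration
#'
#' Collects everything a full synthetic-study run needs: the load design,
#' scenario overrides for the generators, damage-layout parameters and the
#' master seed. Configurations round-trip through YAML
#' ([read_run_config()]).
#'
#' @param forces Normal-force setpoints in mN.
#' @param repeats Repeats per force.
#' @param seed Master RNG seed.
#' @param trace Named list of [trace_scenario()] overrides.
#' @param image Named list of [image_scenario()] overrides.
#' @param layout Named list of [layout_for_pair()] overrides (e.g.
#'   `ref_offset`).
#' @param images Generate and analyse image pairs (set FALSE for a
#'   friction-only run).
#' @param noise_rel Relative force-noise level for the trace design.
#' @return A list of class `run_config`.
#' @export
run_config <- function(forces = c(10, 20, 40, 80), repeats = 9, seed = 1,
                       trace = list(), image = list(), layout = list(),
                       images = TRUE, noise_rel = 0.05) {
  if (length(forces) == 0 || any(forces <= 0)) {
    abort("`forces` must be non-empty and > 0.")
  }
  structure(
    list(forces = as.numeric(forces), repeats = as.integer(repeats),
         seed = as.integer(seed), trace = trace, image = image,
         layout = layout, images = isTRUE(images), noise_rel = noise_rel),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file holding the configuration fields.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full synthetic friction-and-damage pipeline
#'
#' Simulates a matched trace/image study design, runs the friction analysis
#' (height fit, segmentation, slope adjustment, Amonton fits), the damage
#' analysis (detection, fate classification, relative densities) and the
#' Hertz pressure table, and bundles the tidy results with provenance
#' (configuration, seed, package version, and a hash of the result tables
#' that is identical across reruns of the same configuration).
#'
#' Stage failures are collected into the manifest; a partial report is
#' returned rather than aborting the run.
#'
#' @param config A [run_config()] (or path to its YAML form).
#' @return A list of class `report_bundle` with `friction`, `damage`,
#'   `contact`, `manifest` and `provenance`.
#' @examples
#' \donttest{
#' rb <- run_pipeline(run_config(forces = c(10, 40), repeats = 1,
#'                               images = FALSE, seed = 1))
#' rb$friction$fits$dynamic$mu
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  manifest <- list()
  note <- function(stage, status) {
    manifest[[stage]] <<- status
  }

  trace_template <- do.call(trace_scenario, config$trace)
  image_template <- do.call(image_scenario, config$image)
  es <- generate_experiment_set(
    forces = config$forces, repeats = config$repeats,
    trace_template = trace_template, image_template = image_template,
    noise_rel = config$noise_rel, images = config$images, seed = config$seed
  )
  note("simulate", sprintf("ok: %d slides", nrow(es)))

  friction <- tryCatch({
    fb <- batch_friction(es)
    note("friction", sprintf("ok: %d slides, %d failed",
                             nrow(fb$results), nrow(fb$failures)))
    fb
  }, error = function(e) {
    note("friction", paste("failed:", conditionMessage(e)))
    NULL
  })

  damage <- NULL
  if (config$images) {
    damage <- tryCatch({
      db <- do.call(batch_damage, c(list(es), config$layout))
      note("damage", sprintf("ok: %d pairs, %d failed",
                             nrow(db$results), nrow(db$failures)))
      db
    }, error = function(e) {
      note("damage", paste("failed:", conditionMessage(e)))
      NULL
    })
  } else {
    note("damage", "skipped: no images in configuration")
  }

  md <- material_defaults()
  contact <- pressure_sweep(config$forces, list(
    pdms_glass = list(probe = md$probe, m1 = md$glass, m2 = md$pdms),
    ps_glass = list(probe = md$probe, m1 = md$glass, m2 = md$ps)
  ))
  note("contact", sprintf("ok: %d rows", nrow(contact)))

  results_hash <- rlang::hash(list(
    if (!is.null(friction)) friction$results,
    if (!is.null(damage)) damage$results,
    contact
  ))
  structure(
    list(
      friction = friction, damage = damage, contact = contact,
      manifest = manifest,
      provenance = list(
        config = unclass(config), seed = config$seed,
        package_version = as.character(utils::packageVersion("celltribo")),
        timestamp = format(Sys.time(), tz = "UTC"),
        results_hash = results_hash
      )
    ),
    class = "report_bundle"
  )
}

#' Write a report bundle to disk
#'
#' Writes tidy CSVs (per-slide friction and damage rows, per-force
#' summaries, contact table) and a YAML summary with the Amonton fits and
#' provenance.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(bundle$friction)) {
    readr::write_csv(bundle$friction$results, file.path(dir, "friction_slides.csv"))
    readr::write_csv(bundle$friction$summary, file.path(dir, "friction_summary.csv"))
  }
  if (!is.null(bundle$damage)) {
    readr::write_csv(bundle$damage$results, file.path(dir, "damage_slides.csv"))
    readr::write_csv(bundle$damage$summary, file.path(dir, "damage_summary.csv"))
  }
  readr::write_csv(bundle$contact, file.path(dir, "contact_pressures.csv"))
  fits <- bundle$friction$fits
  yaml::write_yaml(list(
    amonton = list(
      mu_s = if (!is.null(fits$static)) fits$static$mu,
      mu_d = if (!is.null(fits$dynamic)) fits$dynamic$mu
    ),
    manifest = bundle$manifest,
    provenance = bundle$provenance
  ), file.path(dir, "report.yaml"))
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  for (stage in names(x$manifest)) {
    cat(sprintf("  %-9s %s\n", stage, x$manifest[[stage]]))
  }
  cat(sprintf("  results hash: %s\n", x$provenance$results_hash))
  invisible(x)
}
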