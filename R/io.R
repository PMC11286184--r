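# Readers and writers: trace CSV + YAML sidecars, 16-bit grayscale TIFF pairs.
#
# Contract: trace CSVs carry the header `time_s,x_mm,h_mm,fx_mN,fz_mN`; other
# tribometer export dialects are mapped onto it via `column_map` and
# `unit_scale`. Readers validate and reject rather than coerce.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' Write a tribometer trace as CSV plus YAML sidecar
#'
#' @param trace A [as_tribo_trace()] object.
#' @param path Output CSV path; a `.yaml` sidecar with the setpoint, speed,
#'   rate and (for synthetic traces) ground truth is written next to it.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tribo_trace"))
  readr::write_csv(tibble::as_tibble(trace), path)
  meta <- trace_meta(trace)
  side <- list(F_N_set_mN = meta$F_N_set, v_t_mm_s = meta$v_t,
               rate_hz = meta$rate)
  gt <- ground_truth(trace)
  if (!is.null(gt)) side$ground_truth <- gt
  yaml::write_yaml(side, sidecar_path(path))
  invisible(path)
}

#' Read a tribometer trace from CSV
#'
#' Reads a delimited trace, optionally mapping a foreign column dialect onto
#' the canonical `time_s, x_mm, h_mm, fx_mN, fz_mN` layout and rescaling
#' units. Metadata come from the YAML sidecar when present, else from the
#' arguments. Malformed input (missing columns, non-monotone time,
#' non-finite values) is rejected with an error naming the offense; units are
#' never guessed.
#'
#' @param path CSV path.
#' @param column_map Optional named character vector mapping canonical names
#'   to file column names, e.g. `c(fx_mN = "Fx_uN")`.
#' @param unit_scale Optional named numeric vector of multipliers applied
#'   after mapping, e.g. `c(fx_mN = 1e-3)` for a file in uN.
#' @param F_N_set,v_t Metadata fallbacks when no sidecar exists.
#' @return A [as_tribo_trace()] object.
#' @export
read_trace <- function(path, column_map = NULL, unit_scale = NULL,
                       F_N_set = NULL, v_t = NULL) {
  if (!file.exists(path)) abort(sprintf("Trace file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        abort(sprintf("Mapped column `%s` (for `%s`) not present in %s.",
                      src, canon, path))
      }
      df[[canon]] <- df[[src]]
    }
  }
  if (!is.null(unit_scale)) {
    for (canon in names(unit_scale)) {
      if (!canon %in% names(df)) {
        abort(sprintf("Cannot rescale missing column `%s`.", canon))
      }
      df[[canon]] <- df[[canon]] * unit_scale[[canon]]
    }
  }
  side <- sidecar_path(path)
  gt <- NULL
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    F_N_set <- F_N_set %||% meta$F_N_set_mN
    v_t <- v_t %||% meta$v_t_mm_s
    gt <- meta$ground_truth
  }
  if (is.null(F_N_set) || is.null(v_t)) {
    abort("Normal-force setpoint and speed required: supply `F_N_set`/`v_t` or a YAML sidecar.")
  }
  as_tribo_trace(df, F_N_set = F_N_set, v_t = v_t, ground_truth = gt)
}

#' Write a blue/red image pair as 16-bit grayscale TIFFs
#'
#' Writes `<basename>_blue.tif` and `<basename>_red.tif` plus a
#' `<basename>.yaml` sidecar recording the pixel size and, for synthetic
#' pairs, the track geometry and force label.
#'
#' @param pair An `image_pair`.
#' @param dir Output directory (created if needed).
#' @param basename File stem.
#' @param F_N Optional normal-force label (mN) recorded in the sidecar.
#' @return The sidecar path, invisibly.
#' @export
write_image_pair <- function(pair, dir, basename, F_N = NULL) {
  stopifnot(inherits(pair, "image_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # images are [x, y]; TIFF stores [row = y, col = x]
  tiff::writeTIFF(t(pair$blue), file.path(dir, paste0(basename, "_blue.tif")),
                  bits.per.sample = 16L)
  tiff::writeTIFF(t(pair$red), file.path(dir, paste0(basename, "_red.tif")),
                  bits.per.sample = 16L)
  side <- list(pixel_size_um = pair$pixel_size)
  s <- pair$scenario
  if (!is.null(s)) {
    side$track_center_y_um <- s$track_center_y
    side$track_width_um <- s$track_width
  }
  if (!is.null(F_N)) side$F_N_mN <- F_N
  side_path <- file.path(dir, paste0(basename, ".yaml"))
  yaml::write_yaml(side, side_path)
  invisible(side_path)
}

#' Read a blue/red image pair from TIFFs plus sidecar
#'
#' @param blue_path,red_path Single-channel TIFF paths (must have identical
#'   dimensions).
#' @param sidecar YAML sidecar path (default: `<blue stem minus _blue>.yaml`);
#'   must record the pixel size.
#' @return An `image_pair` (without per-nucleus ground truth).
#' @export
read_image_pair <- function(blue_path, red_path, sidecar = NULL) {
  for (p in c(blue_path, red_path)) {
    if (!file.exists(p)) abort(sprintf("Image file not found: %s", p))
  }
  blue <- t(tiff::readTIFF(blue_path))
  red <- t(tiff::readTIFF(red_path))
  if (!all(dim(blue) == dim(red))) {
    abort("Blue and red images have mismatched dimensions.")
  }
  if (max(blue) == min(blue) && max(red) == min(red)) {
    warn("Both channels are blank (constant intensity).")
  }
  if (is.null(sidecar)) {
    sidecar <- paste0(sub("_blue$", "", tools::file_path_sans_ext(blue_path)),
                      ".yaml")
  }
  if (!file.exists(sidecar)) {
    abort(sprintf("Sidecar not found: %s (pixel size is required).", sidecar))
  }
  meta <- yaml::read_yaml(sidecar)
  if (is.null(meta$pixel_size_um)) {
    abort("Sidecar does not record `pixel_size_um`.")
  }
  scenario <- NULL
  if (!is.null(meta$track_center_y_um) && !is.null(meta$track_width_um)) {
    scenario <- list(track_center_y = meta$track_center_y_um,
                     track_width = meta$track_width_um)
  }
  structure(
    list(blue = blue, red = red, pixel_size = meta$pixel_size_um,
         truth = NULL, expected = NULL, scenario = scenario,
         F_N = meta$F_N_mN),
    class = "image_pair"
  )
}
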