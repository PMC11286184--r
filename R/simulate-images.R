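# Synthetic two-channel (Hoechst/PI) nuclei micrograph generator.
#
# Image convention used throughout the package: images are numeric matrices
# indexed [x, y] with intensities on a 0-1 scale; the centre of pixel (i, j)
# sits at physical coordinates ((i - 0.5) * pixel_size, (j - 0.5) * pixel_size)
# um, origin at the top-left corner, y increasing downwards.

render_blobs <- function(nx, ny, x_px, y_px, amp, sigma_px) {
  im <- matrix(0, nrow = nx, ncol = ny)
  if (length(x_px) == 0) return(im)
  r <- max(1L, ceiling(4 * sigma_px))
  for (k in seq_along(x_px)) {
    i0 <- max(1L, floor(x_px[k] - r)); i1 <- min(nx, ceiling(x_px[k] + r))
    j0 <- max(1L, floor(y_px[k] - r)); j1 <- min(ny, ceiling(y_px[k] + r))
    if (i0 > i1 || j0 > j1) next
    gx <- exp(-((i0:i1) - x_px[k])^2 / (2 * sigma_px^2))
    gy <- exp(-((j0:j1) - y_px[k])^2 / (2 * sigma_px^2))
    im[i0:i1, j0:j1] <- im[i0:i1, j0:j1] + amp[k] * outer(gx, gy)
  }
  im
}

#' Simulate a blue/red nuclei image pair with a damaged slide track
#'
#' Places nuclei by a homogeneous spatial Poisson process at the reference
#' density, assigns each nucleus inside the track band a fate (removed with
#' `p_remove`, else dead with `p_dead`, else healthy), and renders retained
#' nuclei as isotropic Gaussian blobs: all retained nuclei in the blue
#' (Hoechst) channel, dead nuclei additionally in the red (propidium iodide)
#' channel. Intensities saturate at 1.
#'
#' The per-nucleus ground truth and the expected relative densities inside the
#' track (`rel_blue = (1-p_remove)(1-p_dead)`, `rel_red = (1-p_remove) p_dead`,
#' `rel_removed = p_remove`) are returned alongside the images.
#'
#' @param scenario An [image_scenario()].
#' @return A list of class `image_pair` with elements `blue` and `red`
#'   (matrices indexed `[x, y]`, 0-1 intensities), `pixel_size` (um/px),
#'   `truth` (tibble: `x_um`, `y_um`, `in_track`, `fate`), `expected`
#'   (expected relative densities) and `scenario`.
#' @examples
#' pair <- generate_image_pair(image_scenario(p_remove = 0, p_dead = 0, seed = 1))
#' table(pair$truth$fate)
#' @export
generate_image_pair <- function(scenario) {
  stopifnot(inherits(scenario, "image_scenario"))
  s <- scenario
  with_seed_maybe(s$seed, {
    W <- s$image_width_px * s$pixel_size
    H <- s$image_height_px * s$pixel_size
    area_mm2 <- W * H / 1e6
    n <- rpois(1, s$density_ref * area_mm2)
    x_um <- runif(n, 0, W)
    y_um <- runif(n, 0, H)
    if (s$min_spacing_um > 0 && n > 1) {
      keep <- rep(TRUE, n)
      for (k in 2:n) {
        prev <- which(keep[seq_len(k - 1L)])
        if (length(prev) > 0) {
          d2 <- (x_um[prev] - x_um[k])^2 + (y_um[prev] - y_um[k])^2
          if (min(d2) < s$min_spacing_um^2) keep[k] <- FALSE
        }
      }
      x_um <- x_um[keep]; y_um <- y_um[keep]; n <- length(x_um)
    }

    in_track <- abs(y_um - s$track_center_y) <= s$track_width / 2
    fate <- rep("healthy", n)
    if (n > 0) {
      u_rm <- runif(n); u_dead <- runif(n)
      fate[in_track & u_rm < s$p_remove] <- "removed"
      fate[in_track & u_rm >= s$p_remove & u_dead < s$p_dead] <- "dead"
    }
    truth <- tibble::tibble(x_um = x_um, y_um = y_um,
                            in_track = in_track, fate = fate)

    retained <- fate != "removed"
    dead <- fate == "dead"
    amp <- s$amplitude * runif(n, 0.8, 1.25)
    sigma_px <- s$nucleus_sigma / s$pixel_size
    to_px <- function(u) u / s$pixel_size + 0.5
    nx <- s$image_width_px; ny <- s$image_height_px
    blue <- render_blobs(nx, ny, to_px(x_um[retained]), to_px(y_um[retained]),
                         amp[retained], sigma_px)
    red <- render_blobs(nx, ny, to_px(x_um[dead]), to_px(y_um[dead]),
                        amp[dead], sigma_px)
    finish <- function(im) {
      im <- im + s$background
      if (s$noise_sd > 0) im <- im + rnorm(length(im), 0, s$noise_sd)
      pmin(pmax(im, 0), 1)
    }
    structure(
      list(
        blue = finish(blue), red = finish(red),
        pixel_size = s$pixel_size, truth = truth,
        expected = c(rel_blue = (1 - s$p_remove) * (1 - s$p_dead),
                     rel_red = (1 - s$p_remove) * s$p_dead,
                     rel_removed = s$p_remove),
        scenario = s
      ),
      class = "image_pair"
    )
  })
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %d x %d px @ %g um/px, %d nuclei (%d removed)\n",
              nrow(x$blue), ncol(x$blue), x$pixel_size, nrow(x$truth),
              sum(x$truth$fate == "removed")))
  invisible(x)
}
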