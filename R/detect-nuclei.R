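#' Detect nuclei in a single-channel fluorescence image
#'
#' Standard blob detection for stained nuclei: min-max normalization (making
#' the downstream statistic invariant to intensity rescaling), Gaussian
#' high-pass background subtraction, Gaussian smoothing, Otsu thresholding
#' with a noise-floor guard, watershed splitting of touching blobs on the
#' distance map, and an area filter in physical units. Centroids are returned
#' in micrometres (pixel-centre convention, origin top-left).
#'
#' Touching nuclei closer than roughly the blob width are resolved into one
#' object; this resolution limit is inherent to intensity-based detection.
#'
#' @param image Numeric matrix indexed `[x, y]` with finite intensities.
#' @param pixel_size Pixel size in um/px (required).
#' @param channel Label stored with the detections, e.g. `"blue"` or `"red"`.
#' @param smooth_sigma_um Gaussian smoothing sd in um.
#' @param bg_sigma_um Background (high-pass) Gaussian sd in um.
#' @param min_area_um2,max_area_um2 Area filter bounds in um^2.
#' @param snr_min Objects must exceed the image median by this many robust
#'   SDs; blank or pure-noise images therefore yield an empty set.
#' @param split_tolerance Watershed intensity tolerance (on the normalized
#'   0-1 scale) for splitting touching blobs; smaller values split more
#'   aggressively.
#' @return A tibble of class `nuclei_set` with columns `x_um`, `y_um`,
#'   `area_um2`, `score` (mean smoothed intensity) and `channel`.
#' @examples
#' pair <- generate_image_pair(image_scenario(seed = 1))
#' nrow(detect_nuclei(pair$blue, pair$pixel_size, "blue"))
#' @export
detect_nuclei <- function(image, pixel_size = NULL, channel = "blue",
                          smooth_sigma_um = 2, bg_sigma_um = 25,
                          min_area_um2 = 20, max_area_um2 = 600,
                          snr_min = 5, split_tolerance = 0.02) {
  if (is.null(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` (um/px) is required to detect nuclei in physical units.")
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.")
  }
  empty <- tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                          area_um2 = numeric(0), score = numeric(0),
                          channel = character(0))
  class(empty) <- c("nuclei_set", class(empty))
  rng <- range(image)
  if (!all(is.finite(rng))) abort("`image` contains non-finite values.")
  if (diff(rng) == 0) {
    warn("Image has constant intensity (blank or saturated); returning an empty nuclei set.")
    return(empty)
  }

  im <- (image - rng[1]) / diff(rng)
  bg <- EBImage::gblur(im, sigma = bg_sigma_um / pixel_size)
  sub <- pmax(im - bg, 0)
  sm <- as.matrix(EBImage::gblur(sub, sigma = smooth_sigma_um / pixel_size))

  med <- median(sm)
  noise <- mad(sm)
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  th <- max(th, med + snr_min * max(noise, 1e-6))
  mask <- EBImage::Image(sm > th)
  if (sum(mask) == 0) return(empty)

  # split touching blobs at intensity valleys of the smoothed image
  labels <- EBImage::watershed(EBImage::Image(sm) * mask,
                               tolerance = split_tolerance, ext = 1)
  mom <- EBImage::computeFeatures.moment(labels, sm)
  shp <- EBImage::computeFeatures.shape(labels)
  bas <- EBImage::computeFeatures.basic(labels, sm)
  if (is.null(mom) || nrow(mom) == 0) return(empty)

  area_um2 <- shp[, "s.area"] * pixel_size^2
  keep <- area_um2 >= min_area_um2 & area_um2 <= max_area_um2
  out <- tibble::tibble(
    x_um = (mom[keep, "m.cx"] - 0.5) * pixel_size,
    y_um = (mom[keep, "m.cy"] - 0.5) * pixel_size,
    area_um2 = area_um2[keep],
    score = bas[keep, "b.mean"],
    channel = channel
  )
  class(out) <- c("nuclei_set", class(out))
  out
}
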