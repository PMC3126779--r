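#' Median filter parameters
#'
#' @param width odd window width in pixels (>= 1).
#' @param height odd window height in pixels (>= 1).
#' @param subsample_ratio integer >= 1. With ratio `s > 1` the median is
#'   evaluated only on every s-th row and column and the remaining pixels
#'   copy their nearest evaluated pixel; `s = 1` (default) evaluates every
#'   pixel exactly.
#' @return An object of class `median_params`.
#' @export
median_params <- function(width = 7L, height = 7L, subsample_ratio = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  subsample_ratio <- as.integer(subsample_ratio)
  if (width < 1L || width %% 2L == 0L) stop("`width` must be odd and >= 1")
  if (height < 1L || height %% 2L == 0L) stop("`height` must be odd and >= 1")
  if (subsample_ratio < 1L) stop("`subsample_ratio` must be >= 1")
  structure(list(width = width, height = height,
                 subsample_ratio = subsample_ratio),
            class = "median_params")
}

check_se_fits <- function(img, se) {
  fp <- se$footprint
  if (nrow(fp) > nrow(img$pixels) || ncol(fp) > ncol(img$pixels))
    stop("structuring element is larger than the image")
  invisible(TRUE)
}

with_pixels <- function(img, pixels) {
  out <- img
  out$pixels <- pixels
  out
}

#' Detect dark holes (bottom-hat transform)
#'
#' Converts locally dark blobs - nucleoli inside a brightly stained
#' nucleoplasm - into bright objects: grayscale closing with the disk `se`
#' minus the original image. The response is zero wherever the image is
#' locally flat at the scale of `se` and is non-negative everywhere. The
#' disk diameter must exceed the diameter of the largest hole to be
#' detected (the closing must be able to "roof over" the hole); that is the
#' caller's responsibility.
#'
#' @param img a [calibrated_image()].
#' @param se a [structuring_element()].
#' @return A [calibrated_image()] response, same calibration and depth.
#' @examples
#' px <- matrix(100, 15, 15); px[7:9, 7:9] <- 40
#' img <- calibrated_image(px, 8, "nuclear_marker", 0.2)
#' r <- detect_dark_holes(img, structuring_element(9))
#' r$pixels[8, 8]   # 60
#' @export
detect_dark_holes <- function(img, se) {
  stopifnot(inherits(img, "calibrated_image"),
            inherits(se, "structuring_element"))
  check_se_fits(img, se)
  closed <- .gray_erode_cpp(.gray_dilate_cpp(img$pixels, se$footprint),
                            se$footprint)
  with_pixels(img, pmax(closed - img$pixels, 0))
}

#' Detect light holes (top-hat transform)
#'
#' Dual of [detect_dark_holes()]: bright where the input has locally bright
#' blobs, computed as the original image minus its grayscale opening with
#' `se`. Used when the probe is more concentrated in nucleoli than in the
#' surrounding nucleoplasm (method 5).
#'
#' @inheritParams detect_dark_holes
#' @return A [calibrated_image()] response.
#' @export
detect_light_holes <- function(img, se) {
  stopifnot(inherits(img, "calibrated_image"),
            inherits(se, "structuring_element"))
  check_se_fits(img, se)
  opened <- .gray_dilate_cpp(.gray_erode_cpp(img$pixels, se$footprint),
                             se$footprint)
  with_pixels(img, pmax(img$pixels - opened, 0))
}

#' Pixel-wise image addition
#'
#' Sums two channels of the same scene into a 16-bit container, saturating
#' at 65535. Adding two nucleoplasmic markers that both exclude nucleoli
#' enhances the intensity difference between nucleolus and nucleoplasm
#' before dark-hole detection (method 3).
#'
#' @param a,b [calibrated_image()]s of identical shape and calibration.
#' @return A 16-bit [calibrated_image()]; channel role is taken from `a`.
#' @export
add_images <- function(a, b) {
  stopifnot(inherits(a, "calibrated_image"), inherits(b, "calibrated_image"))
  check_same_geometry(a, b)
  s <- pmin(a$pixels + b$pixels, 65535)
  calibrated_image(s, 16L, a$channel_role, a$pixel_size_um)
}

#' Median filter
#'
#' Replaces each evaluated pixel with the median of the `width x height`
#' window centred on it; windows truncate at the raster border. With a
#' sub-sample ratio `s > 1` the median is evaluated on an s-strided grid
#' only and remaining pixels take the value of their nearest evaluated
#' pixel. Smoothing reduces, but does not fully remove, noise in the hole
#' response; the default 7x7 window at ratio 1 is exact.
#'
#' @param img a [calibrated_image()].
#' @param p a [median_params()].
#' @return A [calibrated_image()].
#' @export
median_filter <- function(img, p = median_params()) {
  stopifnot(inherits(img, "calibrated_image"), inherits(p, "median_params"))
  out <- .median_filter_cpp(img$pixels, p$width, p$height, p$subsample_ratio)
  with_pixels(img, out)
}

#' Binary erosion
#'
#' Classical erosion with a disk: a white pixel stays white only if every
#' neighbour under the footprint is white. Out-of-bounds neighbours are
#' treated as white, so borders behave neutrally. Erosion drives isolated
#' background noise to 0 at the cost of shrinking true objects; pair with
#' [dilate()] to restore object extent.
#'
#' @param mask a [binary_mask()].
#' @param se a [structuring_element()]; the optimal diameter for
#'   nucleolus-scale noise removal is 6.
#' @return A [binary_mask()].
#' @export
erode <- function(mask, se) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "structuring_element"))
  out <- .gray_erode_cpp(mask$pixels + 0, se$footprint)
  binary_mask(out > 0.5, mask$pixel_size_um)
}

#' Binary dilation
#'
#' Dual of [erode()]: a black pixel becomes white if any neighbour under
#' the footprint is white; out-of-bounds neighbours are treated as black.
#' Applied after erosion so the surviving regions regain the extent of the
#' actual nucleolus.
#'
#' @inheritParams erode
#' @return A [binary_mask()].
#' @export
dilate <- function(mask, se) {
  stopifnot(inherits(mask, "binary_mask"), inherits(se, "structuring_element"))
  out <- .gray_dilate_cpp(mask$pixels + 0, se$footprint)
  binary_mask(out > 0.5, mask$pixel_size_um)
}

#' Statistical correction (background subtraction)
#'
#' Subtracts from every pixel the mean intensity of a cell-free region of
#' the same image (interactive mode) or the global mean of a separate
#' cell-free background image (HTS mode). Results clamp at 0: intensities
#' are physical counts. This is the only operation that touches the probe
#' intensities that are later measured; all demarcation filters operate on
#' separate response images.
#'
#' @param img a [calibrated_image()] (typically the probe channel).
#' @param roi cell-free region as `c(row0, col0, row1, col1)`, 0-based
#'   inclusive corners; mutually exclusive with `background`.
#' @param background a cell-free [calibrated_image()] of identical shape
#'   whose global mean is subtracted.
#' @return A corrected [calibrated_image()]; pixel values may be
#'   fractional.
#' @export
statistical_correction <- function(img, roi = NULL, background = NULL) {
  stopifnot(inherits(img, "calibrated_image"))
  if (is.null(roi) == is.null(background))
    stop("supply exactly one of `roi` or `background`")
  if (!is.null(roi)) {
    if (length(roi) != 4L) stop("`roi` must be c(row0, col0, row1, col1)")
    r <- as.integer(roi[c(1, 3)]) + 1L
    cc <- as.integer(roi[c(2, 4)]) + 1L
    if (r[1] > r[2] || cc[1] > cc[2]) stop("empty ROI")
    if (r[1] < 1L || cc[1] < 1L || r[2] > nrow(img$pixels) ||
        cc[2] > ncol(img$pixels))
      stop("ROI lies outside the image")
    bg <- mean(img$pixels[r[1]:r[2], cc[1]:cc[2]])
  } else {
    stopifnot(inherits(background, "calibrated_image"))
    check_same_geometry(img, background)
    bg <- mean(background$pixels)
  }
  with_pixels(img, pmax(img$pixels - bg, 0))
}
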