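#' Calibrated single-channel image
#'
#' The basic raster carried through every stage of the pipeline: a 2-D
#' intensity matrix with a bit depth, a channel role and a spatial
#' calibration in micrometres per pixel edge. Pixel values are non-negative
#' and bounded by `2^bit_depth - 1`; rasters produced by
#' [statistical_correction()] may hold fractional values, integer-valued
#' rasters are enforced only when writing to disk.
#'
#' @param pixels numeric matrix of non-negative intensities (rows = image
#'   rows; coordinates are 0-based `(row, col)` in all reported centroids).
#' @param bit_depth one of 8, 12, 16.
#' @param channel_role one of `"nuclear_marker"`, `"second_marker"`,
#'   `"probe"`.
#' @param pixel_size_um micrometres per pixel edge (> 0). The area of any
#'   pixel set in square micrometres is `count * pixel_size_um^2`.
#' @return An object of class `calibrated_image`.
#' @examples
#' img <- calibrated_image(matrix(0L, 8, 8), 16, "probe", 0.2)
#' @export
calibrated_image <- function(pixels, bit_depth, channel_role, pixel_size_um) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("`pixels` must be a matrix with >= 1 row and >= 1 column")
  storage.mode(pixels) <- "double"
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 12L, 16L))
    stop("`bit_depth` must be one of 8, 12, 16")
  channel_role <- match.arg(channel_role,
                            c("nuclear_marker", "second_marker", "probe"))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixel values must be finite and non-negative")
  if (any(pixels > 2^bit_depth - 1))
    stop("pixel values exceed 2^bit_depth - 1")
  structure(list(pixels = pixels, bit_depth = bit_depth,
                 channel_role = channel_role,
                 pixel_size_um = pixel_size_um),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %d-bit, role=%s, %.4g um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$channel_role,
              x$pixel_size_um))
  cat(sprintf("  intensity range [%.6g, %.6g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary mask
#'
#' Boolean raster sharing the shape contract of the image it derives from;
#' the operand type for [erode()] and [dilate()].
#'
#' @param pixels logical matrix.
#' @param pixel_size_um micrometres per pixel edge.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1))) stop("mask pixels must be logical or 0/1")
    pixels <- pixels > 0
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "binary_mask")
}

#' Label mask
#'
#' Integer raster in which 0 is background and each positive label k is one
#' 8-connected object; label values always form the contiguous set
#' `{0, ..., K}`.
#'
#' @param labels non-negative integer matrix.
#' @param pixel_size_um micrometres per pixel edge.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size_um) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be non-negative")
  u <- sort(unique(as.vector(labels[labels > 0L])))
  if (length(u) && !identical(u, seq_len(max(u))))
    stop("positive labels must form a contiguous set 1..K")
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d objects, %.4g um/px\n",
              nrow(x$labels), ncol(x$labels), max(x$labels),
              x$pixel_size_um))
  invisible(x)
}

#' Number of objects in a label mask
#' @param mask a [label_mask()].
#' @return integer count of positive labels.
#' @export
n_objects <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  max(mask$labels)
}

#' Circular structuring element
#'
#' Discrete disk footprint used by the morphology filters. The footprint is
#' the set of integer offsets `(i, j)` with `i^2 + j^2 <= (diameter/2)^2`,
#' held in an odd-sided logical matrix. `diameter = 1` gives the single
#' centre pixel.
#'
#' @param diameter disk diameter in pixels (>= 1).
#' @param shape only `"circle"` is supported.
#' @return An object of class `structuring_element` (logical footprint
#'   matrix plus metadata).
#' @examples
#' se <- structuring_element(6)
#' sum(se$footprint)
#' @export
structuring_element <- function(diameter, shape = "circle") {
  shape <- match.arg(shape, "circle")
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter < 1)
    stop("`diameter` must be a single number >= 1")
  r <- floor(diameter / 2)
  side <- 2L * as.integer(r) + 1L
  off <- seq_len(side) - (r + 1)
  d2 <- outer(off^2, off^2, "+")
  fp <- d2 <= (diameter / 2)^2
  structure(list(footprint = fp, diameter = diameter, shape = shape),
            class = "structuring_element")
}

# shared shape/calibration guard for binary ops on two rasters
check_same_geometry <- function(a, b) {
  pa <- if (is.list(a)) a$pixels else a
  pb <- if (is.list(b)) b$pixels else b
  if (!all(dim(pa) == dim(pb))) stop("rasters differ in shape")
  if (is.list(a) && is.list(b) &&
      !isTRUE(all.equal(a$pixel_size_um, b$pixel_size_um)))
    stop("rasters differ in pixel_size_um calibration")
  invisible(TRUE)
}

#' Read a grayscale TIFF as a calibrated image
#'
#' Accepts single-plane grayscale TIFFs at 8, 12 or 16 bits per sample. Bit
#' depth is taken from the file. Pixel values are read as stored, without
#' rescaling. The spatial calibration is taken from the TIFF resolution
#' tags when present (inch or cm units); if the file carries no resolution
#' metadata, `pixel_size_um` must be supplied explicitly - there is no
#' silent default.
#'
#' @param path TIFF file path.
#' @param channel_role channel role recorded on the image.
#' @param pixel_size_um calibration override/fallback in micrometres per
#'   pixel; required when the file has no resolution tags.
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, channel_role, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    tiff::readTIFF(path, as.is = TRUE, info = TRUE, all = TRUE),
    error = function(e) stop("unreadable TIFF: ", path, " (", conditionMessage(e), ")"))
  if (is.list(raw)) {
    if (length(raw) > 1L)
      stop("multi-plane TIFF without explicit plane selection: ", path)
    raw <- raw[[1L]]
  }
  if (is.double(unclass(raw)[1]) && !isTRUE(all(raw == floor(raw))))
    stop("float-typed pixels are not supported: ", path)
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3L] != 1L) stop("multi-sample (colour) TIFF not supported: ", path)
    raw <- structure(raw[, , 1L],
                     x.resolution = attr(raw, "x.resolution"),
                     resolution.unit = attr(raw, "resolution.unit"))
  }
  if (!bits %in% c(8L, 12L, 16L))
    stop("unsupported bit depth ", bits, ": ", path)
  ps <- pixel_size_um
  if (is.null(ps)) {
    xres <- attr(raw, "x.resolution")
    unit <- attr(raw, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0 && !is.null(unit)) {
      ps <- switch(unit, cm = 10000 / xres, inch = 25400 / xres, NULL)
    }
    if (is.null(ps))
      stop("TIFF has no usable resolution metadata; supply `pixel_size_um`")
  }
  m <- matrix(as.numeric(raw), nrow(raw), ncol(raw))
  calibrated_image(m, as.integer(bits), channel_role, ps)
}

#' Write a calibrated image as a grayscale TIFF
#'
#' Lossless, uncompressed baseline TIFF at the image's container depth
#' (8-bit images in an 8-bit container, 12- and 16-bit images in a 16-bit
#' container, values unchanged). The calibration is stored in the
#' XResolution/YResolution tags in pixels per centimetre, so
#' `read_image()` recovers `pixel_size_um` without a sidecar. Pixels must
#' be integer-valued.
#'
#' @param img a [calibrated_image()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "calibrated_image"))
  px <- img$pixels
  if (any(px != floor(px)))
    stop("cannot write fractional pixel values; round explicitly first")
  bits <- if (img$bit_depth == 8L) 8L else 16L
  write_baseline_tiff(px, path, bits, img$pixel_size_um)
  invisible(path)
}

# Minimal baseline-TIFF encoder (little-endian, uncompressed, grayscale)
# carrying XResolution/YResolution/ResolutionUnit tags, which the installed
# TIFF writer does not expose. Read back with tiff::readTIFF.
write_baseline_tiff <- function(pixels, path, bits, pixel_size_um) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  con <- file(path, "wb"); on.exit(close(con))
  bytes_px <- bits / 8L
  data_bytes <- nr * nc * bytes_px
  ifd_offset <- 8L + data_bytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  v <- as.integer(t(pixels))                  # TIFF is row-major
  if (bits == 8L) {
    writeBin(as.raw(v), con)
  } else {
    lo <- v %% 256L; hi <- v %/% 256L
    writeBin(as.raw(as.vector(rbind(lo, hi))), con)
  }
  res_num <- round(10000 / pixel_size_um * 1000)  # px per cm, RATIONAL
  res_den <- 1000
  n_tags <- 12L
  rat_offset <- ifd_offset + 2L + n_tags * 12L + 4L
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {                         # SHORT is left-packed
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(n_tags, con, size = 2, endian = "little")
  tag(256, 4, 1, nc)                # ImageWidth
  tag(257, 4, 1, nr)                # ImageLength
  tag(258, 3, 1, bits)              # BitsPerSample
  tag(259, 3, 1, 1)                 # Compression = none
  tag(262, 3, 1, 1)                 # Photometric = BlackIsZero
  tag(273, 4, 1, 8)                 # StripOffsets
  tag(277, 3, 1, 1)                 # SamplesPerPixel
  tag(278, 4, 1, nr)                # RowsPerStrip
  tag(279, 4, 1, data_bytes)        # StripByteCounts
  tag(282, 5, 1, rat_offset)        # XResolution (RATIONAL)
  tag(283, 5, 1, rat_offset + 8L)   # YResolution
  tag(296, 3, 1, 3)                 # ResolutionUnit = cm
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(c(res_num, res_den, res_num, res_den)),
           con, size = 4, endian = "little")
  invisible(path)
}

#' Write a results table to CSV
#'
#' Plain CSV with header, stable column order and full numeric precision
#' (15 significant digits), the on-disk form of every per-object and
#' per-well table the pipeline produces.
#'
#' @param table data frame of measurements.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  fmt <- table
  for (nm in names(fmt)) {
    if (is.double(fmt[[nm]]))
      fmt[[nm]] <- trimws(formatC(fmt[[nm]], digits = 17, format = "g"))
  }
  write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results CSV
#' @param path CSV path written by [write_results()].
#' @return data frame.
#' @export
read_results <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
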