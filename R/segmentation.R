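#' Segmentation parameters
#'
#' Bundles the demarcation method, the hole-response structuring element,
#' the noise-reduction choice and the size/intensity gates applied when
#' segments are generated.
#'
#' @param method_id demarcation strategy 1-5: 1 dark holes on the nuclear
#'   marker, 2 dark holes on the second marker, 3 dark holes on the sum of
#'   both markers, 4 dark holes on the probe, 5 light holes on the probe.
#' @param min_area_um2,max_area_um2 accepted nucleolus area window in
#'   square micrometres (`0 < min < max`).
#' @param intensity_above_background intensity-units gate: a candidate
#'   pixel must exceed the local background of the hole response by at
#'   least this much. Local background is the median response inside the
#'   parent nucleus, recomputed once with candidate pixels excluded.
#' @param noise_filter `"median"` (smooth the grayscale response before
#'   thresholding) or `"erode_dilate"` (threshold first, then open the
#'   binary image with a disk).
#' @param median a [median_params()] used when `noise_filter = "median"`.
#' @param erode_dilate_diameter disk diameter for the erode/dilate
#'   alternative; the optimal diameter is 6.
#' @param se_diameter_px hole-detection disk diameter in pixels; must
#'   exceed the largest expected nucleolus diameter (default 21 px, about
#'   4.2 um at 0.2 um/px).
#' @param nucleus_min_area_um2 minimum accepted nucleus area.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(method_id = 1L,
                                min_area_um2 = 1,
                                max_area_um2 = 8,
                                intensity_above_background = 4000,
                                noise_filter = c("median", "erode_dilate"),
                                median = median_params(),
                                erode_dilate_diameter = 6L,
                                se_diameter_px = 21L,
                                nucleus_min_area_um2 = 40) {
  method_id <- as.integer(method_id)
  if (!method_id %in% 1:5) stop("`method_id` must be in 1..5")
  if (!(min_area_um2 > 0 && min_area_um2 < max_area_um2))
    stop("need 0 < min_area_um2 < max_area_um2")
  if (intensity_above_background < 0)
    stop("`intensity_above_background` must be >= 0")
  noise_filter <- match.arg(noise_filter)
  structure(list(method_id = method_id,
                 min_area_um2 = min_area_um2,
                 max_area_um2 = max_area_um2,
                 intensity_above_background = intensity_above_background,
                 noise_filter = noise_filter,
                 median = median,
                 erode_dilate_diameter = as.integer(erode_dilate_diameter),
                 se_diameter_px = as.integer(se_diameter_px),
                 nucleus_min_area_um2 = nucleus_min_area_um2),
            class = "segmentation_params")
}

#' Label connected components
#'
#' 8-connected (default) component labeling of a binary raster; labels form
#' a contiguous set assigned in raster-scan discovery order.
#'
#' @param mask a [binary_mask()] or logical/0-1 matrix.
#' @param pixel_size_um calibration, required when `mask` is a bare matrix.
#' @param connectivity 8 (default) or 4.
#' @return A [label_mask()].
#' @export
label_components <- function(mask, pixel_size_um = NULL, connectivity = 8L) {
  if (inherits(mask, "binary_mask")) {
    px <- mask$pixels
    pixel_size_um <- mask$pixel_size_um
  } else {
    px <- mask
    if (is.null(pixel_size_um)) stop("supply `pixel_size_um` for bare matrices")
  }
  m <- matrix(as.integer(px > 0), nrow(px), ncol(px))
  label_mask(.label_components_cpp(m, as.integer(connectivity)), pixel_size_um)
}

# 0-based centroids of each positive label; rows ordered by label
object_centroids <- function(labels) {
  K <- max(labels)
  if (K == 0L) return(matrix(numeric(0), 0, 2,
                             dimnames = list(NULL, c("row", "col"))))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  r <- (idx - 1L) %% nrow(labels)
  cc <- (idx - 1L) %/% nrow(labels)
  cbind(row = as.numeric(tapply(r, lab, mean)),
        col = as.numeric(tapply(cc, lab, mean)))
}

# pixel counts per label 1..K
object_sizes <- function(labels) {
  K <- max(labels)
  if (K == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = K)
}

# relabel keeping only `keep` labels, ordered top-to-bottom then
# left-to-right by centroid
relabel_by_centroid <- function(labels, keep = seq_len(max(labels))) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (!length(keep)) return(out)
  cen <- object_centroids(labels)
  keep <- keep[order(cen[keep, 1L], cen[keep, 2L])]
  for (i in seq_along(keep)) out[labels == keep[i]] <- i
  out
}

#' Segment nuclei from the nuclear-marker channel
#'
#' Median-smooths the marker image, thresholds it globally (Otsu), fills
#' interior holes so dark nucleoli belong to their nucleus, labels
#' 8-connected components and removes objects below the minimum nucleus
#' area. The label count is the cell count used by the HTS scoring mode.
#' Nuclei touching the image border are kept and flagged in the
#' `"border_labels"` attribute.
#'
#' @param nuclear_marker a [calibrated_image()] with role
#'   `"nuclear_marker"` (or any nucleoplasmic stain).
#' @param nucleus_min_area_um2 minimum nucleus area in square micrometres.
#' @return A [label_mask()]; a blank image yields an empty mask.
#' @export
segment_nuclei <- function(nuclear_marker, nucleus_min_area_um2 = 40) {
  stopifnot(inherits(nuclear_marker, "calibrated_image"))
  px <- nuclear_marker$pixels
  ps <- nuclear_marker$pixel_size_um
  if (diff(range(px)) == 0)
    return(label_mask(matrix(0L, nrow(px), ncol(px)), ps))
  sm <- .median_filter_cpp(px, 5L, 5L, 1L)
  mx <- 2^nuclear_marker$bit_depth - 1
  th <- EBImage::otsu(sm / mx, range = c(0, 1), levels = 256L)
  fg <- sm / mx > th
  fg <- EBImage::fillHull(matrix(as.integer(fg), nrow(fg), ncol(fg))) > 0
  labs <- .label_components_cpp(matrix(as.integer(fg), nrow(fg), ncol(fg)), 8L)
  sizes <- object_sizes(labs)
  keep <- which(sizes * ps^2 >= nucleus_min_area_um2)
  out <- matrix(0L, nrow(labs), ncol(labs))
  for (i in seq_along(keep)) out[labs == keep[i]] <- i
  border <- unique(c(out[1, ], out[nrow(out), ], out[, 1], out[, ncol(out)]))
  border <- sort(border[border > 0L])
  res <- label_mask(out, ps)
  attr(res, "border_labels") <- border
  res
}

#' Hole-response (demarcation) image for a configured method
#'
#' Produces the grayscale response in which candidate nucleoli appear
#' bright: methods 1-4 apply [detect_dark_holes()] to the nuclear marker,
#' second marker, pixel-wise sum of both markers, or probe respectively;
#' method 5 applies [detect_light_holes()] to the probe.
#'
#' @param channels named list of [calibrated_image()]s with elements among
#'   `nuclear_marker`, `second_marker`, `probe`.
#' @param params a [segmentation_params()].
#' @return A [calibrated_image()] response.
#' @export
demarcation_image <- function(channels, params) {
  stopifnot(inherits(params, "segmentation_params"))
  need <- switch(params$method_id,
                 "nuclear_marker", "second_marker",
                 c("nuclear_marker", "second_marker"), "probe", "probe")
  miss <- setdiff(need, names(channels))
  if (length(miss))
    stop("method ", params$method_id, " requires channel(s): ",
         paste(miss, collapse = ", "))
  se <- structuring_element(params$se_diameter_px)
  src <- switch(params$method_id,
                channels$nuclear_marker,
                channels$second_marker,
                add_images(channels$nuclear_marker, channels$second_marker),
                channels$probe,
                channels$probe)
  if (params$method_id == 5L) detect_light_holes(src, se)
  else detect_dark_holes(src, se)
}

# per-label median of `values` over a label raster; returns vector 1..K
per_label_median <- function(values, labels) {
  K <- max(labels)
  out <- rep(NA_real_, K)
  sel <- labels > 0L
  if (any(sel)) {
    med <- tapply(values[sel], labels[sel], median)
    out[as.integer(names(med))] <- as.numeric(med)
  }
  out
}

#' Segment nucleoli from a hole response
#'
#' Applies the configured noise filter, thresholds the response at
#' local-background + `intensity_above_background`, restricts candidates
#' to pixels inside nuclei, labels 8-connected components and keeps those
#' whose area lies in the configured window. Local background is the
#' median response inside each nucleus, refined once by excluding
#' first-pass candidate pixels. With `nucleus_mask = NULL` (the HTS,
#' probe-only mode) the global median response is the background and no
#' nucleus restriction is applied. Returned labels are ordered
#' deterministically top-to-bottom, then left-to-right by centroid.
#'
#' @param response hole-response [calibrated_image()] from
#'   [demarcation_image()].
#' @param nucleus_mask a [label_mask()] of nuclei, or `NULL`.
#' @param params a [segmentation_params()].
#' @return A [label_mask()] of accepted nucleolus segments.
#' @export
segment_nucleoli <- function(response, nucleus_mask, params) {
  stopifnot(inherits(response, "calibrated_image"),
            inherits(params, "segmentation_params"))
  ps <- response$pixel_size_um
  resp <- response$pixels
  gate <- params$intensity_above_background

  threshold_pass <- function(r, exclude = NULL) {
    if (is.null(nucleus_mask)) {
      vals <- if (is.null(exclude)) r else r[!exclude]
      bg <- median(vals)
      r >= bg + gate
    } else {
      labs <- nucleus_mask$labels
      use <- labs > 0L
      if (!is.null(exclude)) use <- use & !exclude
      bg <- rep(NA_real_, max(labs))
      if (any(use)) {
        med <- tapply(r[use], labs[use], median)
        bg[as.integer(names(med))] <- as.numeric(med)
      }
      cand <- matrix(FALSE, nrow(r), ncol(r))
      inside <- labs > 0L
      cand[inside] <- r[inside] >= bg[labs[inside]] + gate
      cand[is.na(cand)] <- FALSE
      cand
    }
  }

  if (params$noise_filter == "median") {
    resp <- .median_filter_cpp(resp, params$median$width,
                               params$median$height,
                               params$median$subsample_ratio)
    cand <- threshold_pass(resp)
    cand <- threshold_pass(resp, exclude = cand)
  } else {
    cand <- threshold_pass(resp)
    cand <- threshold_pass(resp, exclude = cand)
    se <- structuring_element(params$erode_dilate_diameter)
    m <- binary_mask(cand, ps)
    cand <- dilate(erode(m, se), se)$pixels
    if (!is.null(nucleus_mask)) cand <- cand & nucleus_mask$labels > 0L
  }

  labs <- .label_components_cpp(matrix(as.integer(cand), nrow(cand),
                                       ncol(cand)), 8L)
  if (max(labs) == 0L) return(label_mask(labs, ps))
  areas <- object_sizes(labs) * ps^2
  keep <- which(areas >= params$min_area_um2 & areas <= params$max_area_um2)
  label_mask(relabel_by_centroid(labs, keep), ps)
}

#' Assign nucleoli to parent nuclei
#'
#' Each nucleolus is attached to the nucleus containing its centroid
#' (nearest-pixel lookup). Nucleoli whose centroid falls outside every
#' nucleus are dropped; the number dropped is reported in the
#' `"n_dropped"` attribute.
#'
#' @param nucleolus_mask a [label_mask()] of nucleolus segments.
#' @param nucleus_mask a [label_mask()] of nuclei, same shape.
#' @return Named integer vector mapping nucleolus label -> nucleus label
#'   (dropped nucleoli omitted), with attribute `n_dropped`.
#' @export
assign_parents <- function(nucleolus_mask, nucleus_mask) {
  stopifnot(inherits(nucleolus_mask, "label_mask"),
            inherits(nucleus_mask, "label_mask"))
  check_same_geometry(list(pixels = nucleolus_mask$labels),
                      list(pixels = nucleus_mask$labels))
  K <- max(nucleolus_mask$labels)
  if (K == 0L) {
    out <- integer(0)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  cen <- object_centroids(nucleolus_mask$labels)
  ri <- pmin(pmax(round(cen[, 1L]) + 1L, 1L), nrow(nucleus_mask$labels))
  ci <- pmin(pmax(round(cen[, 2L]) + 1L, 1L), ncol(nucleus_mask$labels))
  parent <- nucleus_mask$labels[cbind(ri, ci)]
  ok <- parent > 0L
  out <- parent[ok]
  names(out) <- which(ok)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Run a full demarcation + quantification method on one scene
#'
#' Executes the three-step workflow end to end: nucleus segmentation from
#' the nuclear marker, hole-response demarcation for the configured
#' method, noise filtering and constrained segmentation, parent
#' assignment, statistical correction of the probe, and per-object
#' measurement. The result is deterministic: identical inputs and
#' configuration give bit-identical tables.
#'
#' @param channels named list of [calibrated_image()]s (`nuclear_marker`,
#'   optionally `second_marker`, `probe`).
#' @param params a [segmentation_params()].
#' @param correction list with either `roi = c(row0, col0, row1, col1)`
#'   (cell-free region of the probe image) or `background =` a cell-free
#'   [calibrated_image()].
#' @return List with elements `segmentation` (nucleus/nucleolus
#'   [label_mask()]s plus `parent_of`), `corrected_probe`, `nucleoli`
#'   (per-nucleolus data frame) and `nuclei` (per-nucleus data frame).
#' @export
run_method <- function(channels, params, correction) {
  stopifnot(inherits(params, "segmentation_params"))
  if (is.null(channels$probe)) stop("a `probe` channel is required")
  if (is.null(channels$nuclear_marker))
    stop("a `nuclear_marker` channel is required for nucleus segmentation")
  nuc <- segment_nuclei(channels$nuclear_marker,
                        params$nucleus_min_area_um2)
  resp <- demarcation_image(channels, params)
  nol <- segment_nucleoli(resp, nuc, params)
  parent <- assign_parents(nol, nuc)
  keep <- as.integer(names(parent))
  relab <- relabel_by_centroid(nol$labels, keep)
  # parent vector follows the same centroid ordering as the relabeling
  if (length(keep)) {
    cen <- object_centroids(nol$labels)
    ord <- order(cen[keep, 1L], cen[keep, 2L])
    parent_of <- as.integer(parent[ord])
    names(parent_of) <- seq_along(parent_of)
  } else {
    parent_of <- integer(0)
  }
  nol <- label_mask(relab, nol$pixel_size_um)
  seg <- structure(list(nucleus_mask = nuc, nucleolus_mask = nol,
                        parent_of = parent_of,
                        n_dropped = attr(parent, "n_dropped")),
                   class = "scene_segmentation")
  corrected <- statistical_correction(channels$probe,
                                      roi = correction$roi,
                                      background = correction$background)
  meas <- measure_objects(corrected, seg)
  list(segmentation = seg, corrected_probe = corrected,
       nucleoli = meas$nucleoli, nuclei = meas$nuclei)
}
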