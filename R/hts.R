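#' Plate layout for HTS scoring
#'
#' Maps wells to treatment labels and replicate/experiment indices and
#' records which vehicle control each treatment is compared against
#' (e.g. water for cycloheximide, DMSO for the other compounds).
#'
#' @param wells data frame with columns `well`, `treatment` and optionally
#'   `experiment` (replicate experiment index, default 1).
#' @param sites_per_well number of imaged regions per well (2-4 typical).
#' @param vehicle_map named character vector, treatment -> vehicle
#'   treatment label; vehicles map to themselves implicitly.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(wells, sites_per_well = 2L, vehicle_map) {
  stopifnot(is.data.frame(wells),
            all(c("well", "treatment") %in% names(wells)))
  if (!"experiment" %in% names(wells)) wells$experiment <- 1L
  if (anyDuplicated(paste(wells$well, wells$experiment)))
    stop("duplicated well/experiment combination")
  trts <- unique(wells$treatment)
  vehicles <- unique(unname(vehicle_map))
  for (tr in setdiff(trts, vehicles)) {
    if (!tr %in% names(vehicle_map))
      stop("treatment without a mapped vehicle control: ", tr)
    if (!vehicle_map[[tr]] %in% trts)
      stop("vehicle '", vehicle_map[[tr]], "' for treatment '", tr,
           "' is not on the plate")
  }
  structure(list(wells = wells, sites_per_well = as.integer(sites_per_well),
                 vehicle_map = vehicle_map),
            class = "plate_layout")
}

#' Score one imaged site (HTS mode)
#'
#' Fully automated probe-only scoring: the cell-free background image's
#' mean is subtracted from the probe, light holes are detected on the
#' corrected probe, the response is median-smoothed and thresholded at
#' global background + the intensity gate, and segments inside the
#' configured area window (2-5 um^2 by default) are counted as nucleoli -
#' no nucleus mask restricts the detection. Cells are counted from the
#' DAPI channel.
#'
#' @param probe probe [calibrated_image()].
#' @param dapi nuclear-marker [calibrated_image()] used only for the cell
#'   count.
#' @param background_image cell-free [calibrated_image()], same shape as
#'   the probe; required in HTS mode.
#' @param params a [segmentation_params()]; `method_id` is forced to 5
#'   and the default area window is the HTS window `[2, 5]` um^2.
#' @return List (`site_score`) with `n_cells`, `n_nucleoli`, `areas_um2`,
#'   `mean_intensities`.
#' @export
score_site <- function(probe, dapi, background_image,
                       params = segmentation_params(method_id = 5L,
                                                    min_area_um2 = 2,
                                                    max_area_um2 = 5)) {
  if (is.null(background_image))
    stop("HTS mode requires a cell-free background image")
  stopifnot(inherits(probe, "calibrated_image"),
            inherits(dapi, "calibrated_image"))
  corrected <- statistical_correction(probe, background = background_image)
  se <- structuring_element(params$se_diameter_px)
  resp <- detect_light_holes(corrected, se)
  p5 <- params; p5$method_id <- 5L
  nol <- segment_nucleoli(resp, nucleus_mask = NULL, p5)
  n_cells <- n_objects(segment_nuclei(dapi, params$nucleus_min_area_um2))
  K <- n_objects(nol)
  if (K > 0L) {
    sel <- nol$labels > 0L
    lab <- nol$labels[sel]
    area <- tabulate(lab, nbins = K) * nol$pixel_size_um^2
    integ <- as.numeric(rowsum(corrected$pixels[sel], lab))
    mi <- integ / area
  } else {
    area <- numeric(0); mi <- numeric(0)
  }
  structure(list(n_cells = n_cells, n_nucleoli = K,
                 areas_um2 = area, mean_intensities = mi),
            class = "site_score")
}

#' Pool site scores into a well score
#'
#' Sites visited in the same well are pooled before well statistics are
#' computed: cell and nucleolus counts are summed and the per-object area
#' and intensity vectors concatenated.
#'
#' @param site_scores list of `site_score`s from [score_site()].
#' @param well well identifier.
#' @param small_threshold_um2 area threshold for the fraction-small
#'   statistic (default 4 um^2).
#' @return One-row data frame: `well`, `n_cells`, `n_nucleoli`,
#'   `nucleoli_per_cell`, `pct_area_below_threshold`,
#'   `mean_pixel_intensity`, `mean_area_um2`.
#' @export
score_well <- function(site_scores, well = NA_character_,
                       small_threshold_um2 = 4) {
  areas <- unlist(lapply(site_scores, `[[`, "areas_um2"))
  mis <- unlist(lapply(site_scores, `[[`, "mean_intensities"))
  n_cells <- sum(vapply(site_scores, `[[`, integer(1), "n_cells"))
  n_nol <- sum(vapply(site_scores, `[[`, integer(1), "n_nucleoli"))
  data.frame(well = well,
             n_cells = n_cells,
             n_nucleoli = n_nol,
             nucleoli_per_cell = if (n_cells > 0) n_nol / n_cells else NA_real_,
             pct_area_below_threshold =
               if (n_nol > 0) fraction_small(areas, small_threshold_um2)
               else NA_real_,
             mean_pixel_intensity = if (n_nol > 0) mean(mis) else NA_real_,
             mean_area_um2 = if (n_nol > 0) mean(areas) else NA_real_)
}

#' Percentage of nucleoli below an area threshold
#'
#' A simple and fast plate-scale readout of nucleolar shrinkage:
#' `100 * |{a < threshold}| / |areas|`. With the detection window at
#' 2-5 um^2 and the threshold at 4 um^2, drug-induced shrinkage raises
#' this percentage.
#'
#' @param areas numeric vector of nucleolar areas in um^2.
#' @param threshold_um2 threshold (default 4), normally inside the
#'   detection window.
#' @return Percentage in [0, 100]; `NA` with a warning for empty input.
#' @export
fraction_small <- function(areas, threshold_um2 = 4) {
  if (!length(areas)) {
    warning("fraction_small: empty area list; result undefined")
    return(NA_real_)
  }
  100 * sum(areas < threshold_um2) / length(areas)
}

#' Aggregate well scores per treatment
#'
#' Computes mean and sample STDEV of each well statistic across replicate
#' units (whole experiments by default, individual wells optionally),
#' normalizes every treatment to its mapped vehicle control and tests it
#' against that vehicle with a two-tailed Student's t-test. A one-way
#' ANOVA p-value across all treatments sharing a vehicle is attached as
#' the `"anova"` attribute.
#'
#' @param scores data frame of well scores ([score_well()] rows) joined
#'   with `treatment` and `experiment` columns.
#' @param layout a [plate_layout()].
#' @param statistic which well statistic to aggregate (default
#'   `"pct_area_below_threshold"`).
#' @param unit replication unit: `"experiment"` (mean over wells within
#'   each experiment first; default) or `"well"`.
#' @return Data frame with one row per treatment: n units, mean, sd,
#'   normalized mean (vehicle = 1) and p-value vs the vehicle.
#' @export
aggregate_treatments <- function(scores, layout,
                                 statistic = "pct_area_below_threshold",
                                 unit = c("experiment", "well")) {
  stopifnot(inherits(layout, "plate_layout"),
            statistic %in% names(scores))
  unit <- match.arg(unit)
  if (!"treatment" %in% names(scores)) stop("scores lack a treatment column")
  if (!"experiment" %in% names(scores)) scores$experiment <- 1L
  vals <- scores[[statistic]]
  if (unit == "experiment") {
    agg <- aggregate(vals,
                     by = list(treatment = scores$treatment,
                               experiment = scores$experiment),
                     FUN = mean)
    units <- split(agg$x, agg$treatment)
  } else {
    units <- split(vals, scores$treatment)
  }
  vm <- layout$vehicle_map
  vehicle_of <- function(tr) if (tr %in% names(vm)) vm[[tr]] else tr
  rows <- lapply(names(units), function(tr) {
    v <- units[[tr]]
    veh <- vehicle_of(tr)
    if (!veh %in% names(units)) stop("treatment '", tr, "' has no control")
    ctrl <- units[[veh]]
    norm <- mean(v) / mean(ctrl)
    p <- if (tr == veh) 1
         else if (length(v) >= 2L && length(ctrl) >= 2L)
           compare_groups(v, ctrl)$p
         else NA_real_
    data.frame(treatment = tr, vehicle = veh, n = length(v),
               mean = mean(v), sd = if (length(v) >= 2L) sd(v) else NA_real_,
               normalized_mean = norm, p_value = p)
  })
  out <- do.call(rbind, rows)
  # one-way ANOVA across the treatments sharing each vehicle
  anovas <- lapply(unique(vapply(names(units), vehicle_of, character(1))),
                   function(veh) {
    members <- names(units)[vapply(names(units), vehicle_of,
                                   character(1)) == veh]
    if (length(members) < 3L) return(NULL)
    g <- units[members]
    if (any(vapply(g, length, integer(1)) < 2L)) return(NULL)
    cmp <- compare_groups(groups = g)
    data.frame(vehicle = veh, F = cmp$statistic, p_value = cmp$p)
  })
  attr(out, "anova") <- do.call(rbind, anovas)
  out
}

#' Z-factor assay quality
#'
#' Screening-window statistic `Z = 1 - 3 (sigma_pos + sigma_neg) /
#' |mu_pos - mu_neg|` computed with sample (n-1) standard deviations. A
#' noise-free assay gives Z = 1; Z >= 0.5 classifies an assay as
#' excellent for screening, 0 < Z < 0.5 as moderate, Z <= 0 as
#' unsuitable. Z is invariant under a common shift and positive rescaling
#' of both groups.
#'
#' @param pos_values scored statistic for positive-control replicates
#'   (>= 2 values).
#' @param neg_values scored statistic for negative-control replicates
#'   (>= 2 values).
#' @return List (`assay_quality`): `mu_pos`, `sigma_pos`, `mu_neg`,
#'   `sigma_neg`, `z_factor`, `quality`.
#' @examples
#' z_factor(c(95, 100, 105), c(15, 20, 25))
#' @export
z_factor <- function(pos_values, neg_values) {
  if (length(pos_values) < 2L || length(neg_values) < 2L)
    stop("need >= 2 values per control group")
  mu_p <- mean(pos_values); mu_n <- mean(neg_values)
  if (mu_p == mu_n)
    stop("positive and negative control means are equal; Z undefined")
  s_p <- sd(pos_values); s_n <- sd(neg_values)
  z <- 1 - 3 * (s_p + s_n) / abs(mu_p - mu_n)
  quality <- if (z >= 0.5) "excellent" else if (z > 0) "moderate"
             else "unsuitable"
  structure(list(mu_pos = mu_p, sigma_pos = s_p, mu_neg = mu_n,
                 sigma_neg = s_n, z_factor = z, quality = quality),
            class = "assay_quality")
}

#' @export
print.assay_quality <- function(x, ...) {
  cat(sprintf("Z-factor: %.3f (%s)\n", x$z_factor, x$quality))
  cat(sprintf("  positive controls: mean %.4g, sd %.4g\n", x$mu_pos,
              x$sigma_pos))
  cat(sprintf("  negative controls: mean %.4g, sd %.4g\n", x$mu_neg,
              x$sigma_neg))
  invisible(x)
}

#' Score a synthetic (or real) plate of images
#'
#' Headless batch scoring: every well/site image pair is scored with
#' [score_site()], sites are pooled per well, and treatment labels from
#' the layout are attached. Reruns with identical inputs give
#' bit-identical tables.
#'
#' @param plate list as produced by [generate_plate()]: `sites` (each
#'   with `well`, `site`, `experiment`, `channels`) and `background`
#'   image.
#' @param layout a [plate_layout()].
#' @param params `segmentation_params` for [score_site()].
#' @param small_threshold_um2 threshold for the fraction-small statistic.
#' @return Data frame of well scores with `treatment` and `experiment`.
#' @export
score_plate <- function(plate, layout,
                        params = segmentation_params(method_id = 5L,
                                                     min_area_um2 = 2,
                                                     max_area_um2 = 5),
                        small_threshold_um2 = 4) {
  by_well <- split(plate$sites,
                   vapply(plate$sites, function(s)
                     paste(s$well, s$experiment, sep = "\r"), character(1)))
  rows <- lapply(by_well, function(sites) {
    ss <- lapply(sites, function(s)
      score_site(s$channels$probe, s$channels$nuclear_marker,
                 plate$background, params))
    row <- score_well(ss, well = sites[[1L]]$well, small_threshold_um2)
    row$experiment <- sites[[1L]]$experiment
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  key <- paste(layout$wells$well, layout$wells$experiment)
  out$treatment <- layout$wells$treatment[match(paste(out$well,
                                                      out$experiment), key)]
  out[order(out$experiment, out$well), , drop = FALSE]
}
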