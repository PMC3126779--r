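#' Measure nucleolus and nucleus fluorescence
#'
#' Computes per-object statistics from the statistically corrected probe
#' image: for every nucleolus the area (um^2), integrated intensity (sum
#' of corrected probe pixels) and mean intensity (integrated / area, i.e.
#' per um^2); for every nucleus the filled-mask area and integrated
#' intensity plus the sums over its member nucleoli, the per-nucleus mean
#' (nucleolar sum intensity / nucleolar sum area) and the
#' nucleolar/nuclear ratio of integrated intensities.
#'
#' @param corrected_probe probe [calibrated_image()] after
#'   [statistical_correction()].
#' @param seg a `scene_segmentation` as returned inside [run_method()],
#'   i.e. a list with `nucleus_mask`, `nucleolus_mask` and `parent_of`.
#' @return List of two data frames, `nucleoli` and `nuclei`.
#' @export
measure_objects <- function(corrected_probe, seg) {
  stopifnot(inherits(corrected_probe, "calibrated_image"))
  px <- corrected_probe$pixels
  ps <- corrected_probe$pixel_size_um
  nol <- seg$nucleolus_mask$labels
  nuc <- seg$nucleus_mask$labels
  check_same_geometry(list(pixels = px), list(pixels = nol))
  check_same_geometry(list(pixels = px), list(pixels = nuc))

  Kno <- max(nol)
  if (Kno > 0L) {
    sel <- nol > 0L
    lab <- nol[sel]
    area_px <- tabulate(lab, nbins = Kno)
    integ <- as.numeric(rowsum(px[sel], lab))
    cen <- object_centroids(nol)
    area_um2 <- area_px * ps^2
    nucleoli <- data.frame(
      nucleolus_id = seq_len(Kno),
      nucleus_id = as.integer(
        if (is.null(names(seg$parent_of))) seg$parent_of[seq_len(Kno)]
        else seg$parent_of[as.character(seq_len(Kno))]),
      area_um2 = area_um2,
      integrated_intensity = integ,
      mean_intensity = integ / area_um2,
      centroid_row = cen[, 1L],
      centroid_col = cen[, 2L])
  } else {
    nucleoli <- data.frame(nucleolus_id = integer(0), nucleus_id = integer(0),
                           area_um2 = numeric(0),
                           integrated_intensity = numeric(0),
                           mean_intensity = numeric(0),
                           centroid_row = numeric(0), centroid_col = numeric(0))
  }

  Knu <- max(nuc)
  if (Knu > 0L) {
    sel <- nuc > 0L
    lab <- nuc[sel]
    n_area_px <- tabulate(lab, nbins = Knu)
    n_integ <- as.numeric(rowsum(px[sel], lab))
    sum_int <- rep(0, Knu); sum_area <- rep(0, Knu); n_no <- rep(0L, Knu)
    if (Kno > 0L) {
      agg_i <- tapply(nucleoli$integrated_intensity, nucleoli$nucleus_id, sum)
      agg_a <- tapply(nucleoli$area_um2, nucleoli$nucleus_id, sum)
      agg_n <- tapply(nucleoli$nucleolus_id, nucleoli$nucleus_id, length)
      ids <- as.integer(names(agg_i))
      sum_int[ids] <- as.numeric(agg_i)
      sum_area[ids] <- as.numeric(agg_a)
      n_no[ids] <- as.integer(agg_n)
    }
    ratio <- ifelse(n_integ > 0, sum_int / n_integ, NA_real_)
    nuclei <- data.frame(
      nucleus_id = seq_len(Knu),
      nuclear_area_um2 = n_area_px * ps^2,
      nuclear_integrated_intensity = n_integ,
      n_nucleoli = n_no,
      nucleolar_sum_intensity = sum_int,
      nucleolar_sum_area = sum_area,
      per_nucleus_mean = ifelse(sum_area > 0, sum_int / sum_area, NA_real_),
      nucleolar_nuclear_ratio = ratio,
      ratio_flagged = n_integ <= 0)
  } else {
    nuclei <- data.frame(nucleus_id = integer(0), nuclear_area_um2 = numeric(0),
                         nuclear_integrated_intensity = numeric(0),
                         n_nucleoli = integer(0),
                         nucleolar_sum_intensity = numeric(0),
                         nucleolar_sum_area = numeric(0),
                         per_nucleus_mean = numeric(0),
                         nucleolar_nuclear_ratio = numeric(0),
                         ratio_flagged = logical(0))
  }
  list(nucleoli = nucleoli, nuclei = nuclei)
}

condition_summary <- function(values, condition, control,
                              var_equal = TRUE) {
  condition <- as.character(condition)
  if (!control %in% condition) stop("unknown control label: ", control)
  labs <- unique(condition)
  ctrl_vals <- values[condition == control]
  ctrl_mean <- mean(ctrl_vals)
  rows <- lapply(labs, function(lb) {
    v <- values[condition == lb]
    if (length(v) < 2L) stop("condition '", lb, "' has fewer than 2 objects")
    cmp <- if (lb == control) list(statistic = 0, p = 1)
           else compare_groups(v, ctrl_vals, var_equal = var_equal)
    data.frame(condition = lb, n = length(v), mean = mean(v), sd = sd(v),
               sem = sd(v) / sqrt(length(v)),
               normalized_mean = if (lb == control) 1 else mean(v) / ctrl_mean,
               statistic = cmp$statistic, p_value = cmp$p)
  })
  do.call(rbind, rows)
}

#' Per-nucleolus condition analysis
#'
#' Summarises per-nucleolus mean intensities by condition; every nucleolus
#' carries the same weight regardless of how many share a nucleus. Means
#' are normalized so the control condition is exactly 1, and each
#' condition is compared to the control by a two-tailed two-sample t-test
#' (pooled variance by default).
#'
#' @param records per-nucleolus data frame from [measure_objects()] (or a
#'   row-bound set of them).
#' @param conditions condition label per record; defaults to a
#'   `condition` column of `records`.
#' @param control control condition label.
#' @param var_equal pooled-variance Student's t (default) or Welch.
#' @return Data frame with one row per condition: n, mean, sd, sem,
#'   normalized mean, test statistic and p-value vs control.
#' @export
per_nucleolus_analysis <- function(records, conditions = records$condition,
                                   control, var_equal = TRUE) {
  if (is.null(conditions)) stop("no condition labels supplied")
  condition_summary(records$mean_intensity, conditions, control, var_equal)
}

#' Per-nucleus condition analysis
#'
#' As [per_nucleolus_analysis()], but measurements for nucleoli in the
#' same nucleus are combined into one data point per nucleus:
#' `nucleolar_sum_intensity / nucleolar_sum_area`. Nuclei with no detected
#' nucleoli are excluded (and simply absent from the unit count).
#'
#' @param records per-nucleus data frame from [measure_objects()].
#' @inheritParams per_nucleolus_analysis
#' @return Data frame as in [per_nucleolus_analysis()].
#' @export
per_nucleus_analysis <- function(records, conditions = records$condition,
                                 control, var_equal = TRUE) {
  if (is.null(conditions)) stop("no condition labels supplied")
  keep <- records$n_nucleoli > 0
  condition_summary(records$per_nucleus_mean[keep], conditions[keep],
                    control, var_equal)
}

#' Nucleolar/nuclear intensity ratio
#'
#' Per nucleus, the integrated nucleolar probe intensity divided by the
#' integrated nuclear probe intensity - a compartmentalization readout
#' that lies in [0, 1] when nucleoli are contained in their nucleus and
#' intensities are non-negative. Nuclei with zero nuclear intensity are
#' flagged and their ratio is `NA`.
#'
#' @param records per-nucleus data frame from [measure_objects()].
#' @param per_area if `TRUE`, use per-area (mean) rather than integrated
#'   intensities in both numerator and denominator.
#' @return Data frame with `nucleus_id`, `ratio`, `flagged`.
#' @export
nucleolar_nuclear_ratio <- function(records, per_area = FALSE) {
  num <- records$nucleolar_sum_intensity
  den <- records$nuclear_integrated_intensity
  if (per_area) {
    num <- num / records$nucleolar_sum_area
    den <- den / records$nuclear_area_um2
  }
  flagged <- !(den > 0) | !is.finite(den)
  data.frame(nucleus_id = records$nucleus_id,
             ratio = ifelse(flagged, NA_real_, num / den),
             flagged = flagged)
}

#' Within-nucleus variability of nucleolar intensity
#'
#' For every nucleus holding at least two nucleoli, the sample standard
#' deviation of its member per-nucleolus mean intensities expressed as a
#' percentage of their mean; the condition value is the average over such
#' nuclei. Quantifies how much individual nucleoli in the same nucleus
#' differ in the concentration of the probed molecule.
#'
#' @param records per-nucleolus data frame from [measure_objects()].
#' @param conditions condition label per record; defaults to a
#'   `condition` column, or a single unnamed condition when absent.
#' @return Data frame with `condition`, `n_nuclei` (nuclei entering the
#'   average) and `stdev_pct`.
#' @export
within_nucleus_variability <- function(records,
                                       conditions = records$condition) {
  if (is.null(conditions)) conditions <- rep("all", nrow(records))
  conditions <- as.character(conditions)
  out <- lapply(unique(conditions), function(lb) {
    r <- records[conditions == lb, ]
    key <- r$nucleus_id
    pcts <- vapply(unique(key), function(k) {
      v <- r$mean_intensity[key == k]
      if (length(v) < 2L) return(NA_real_)
      100 * sd(v) / mean(v)
    }, numeric(1))
    pcts <- pcts[!is.na(pcts)]
    data.frame(condition = lb, n_nuclei = length(pcts),
               stdev_pct = if (length(pcts)) mean(pcts) else NA_real_)
  })
  do.call(rbind, out)
}

#' Histogram with bins shared across conditions
#'
#' Bins values on a common set of edges so frequency distributions of
#' different conditions are directly comparable. Bins are right-open
#' `[e_i, e_{i+1})` except the last, which is closed so the maximum edge
#' is counted.
#'
#' @param values numeric vector.
#' @param conditions condition label per value (a single condition when
#'   omitted).
#' @param breaks either a number of equal-width bins spanning the pooled
#'   range, or an explicit vector of edges.
#' @return List with `breaks` (edges) and `counts` (matrix, one row per
#'   bin, one column per condition).
#' @export
histogram_counts <- function(values, conditions = NULL, breaks = 10) {
  if (!length(values)) stop("empty input")
  if (is.null(conditions)) conditions <- rep("all", length(values))
  conditions <- as.character(conditions)
  if (length(breaks) == 1L) {
    rng <- range(values)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = breaks + 1L)
  }
  labs <- unique(conditions)
  nb <- length(breaks) - 1L
  counts <- sapply(labs, function(lb) {
    v <- values[conditions == lb]
    idx <- findInterval(v, breaks, rightmost.closed = TRUE)
    tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  })
  counts <- matrix(counts, nrow = nb, dimnames = list(NULL, labs))
  list(breaks = breaks, counts = counts)
}

#' Compare groups of measurements
#'
#' Two groups: two-tailed two-sample t-test, pooled variance by default
#' (Welch with `var_equal = FALSE`). More than two groups: one-way ANOVA.
#' Groups that are all identical yield statistic 0 and p = 1 rather than
#' an error.
#'
#' @param a,b numeric vectors (two-group form), or
#' @param groups list of numeric vectors (>= 2 values each).
#' @param var_equal pooled (TRUE) vs Welch t-test.
#' @return List with `statistic` (t or F), `p`, `df`.
#' @export
compare_groups <- function(a = NULL, b = NULL, groups = NULL,
                           var_equal = TRUE) {
  if (is.null(groups)) groups <- list(a, b)
  groups <- groups[!vapply(groups, is.null, logical(1))]
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs >= 2 values")
  if (length(groups) == 2L) {
    x <- groups[[1L]]; y <- groups[[2L]]
    if (sd(c(x, y)) == 0)
      return(list(statistic = 0, p = 1,
                  df = length(x) + length(y) - 2L))
    tt <- t.test(x, y, var.equal = var_equal, alternative = "two.sided")
    list(statistic = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter))
  } else {
    v <- unlist(groups)
    g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
    if (sd(v) == 0)
      return(list(statistic = 0, p = 1, df = c(length(groups) - 1L,
                                               length(v) - length(groups))))
    fit <- aov(v ~ g)
    s <- summary(fit)[[1L]]
    list(statistic = s[["F value"]][1L], p = s[["Pr(>F)"]][1L],
         df = s[["Df"]])
  }
}
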