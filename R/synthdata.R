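#' Parameters for the synthetic field generator
#'
#' Describes a synthetic multi-channel fluorescence field: elliptical
#' nuclei rendered at a nucleoplasmic marker level, nucleoli rendered as
#' multiplicative dark holes in the marker channels and as enriched or
#' depleted regions in the probe channel, plus background offset, optional
#' linear gradient and seeded noise. Defaults describe the package's
#' reference validation field: 20 nuclei of HeLa-like size, 2-3 nucleoli
#' each with areas spanning the 2-5 um^2 screening window, marker hole
#' depth 0.5, and Gaussian noise with sigma equal to 2% of the dynamic
#' range (the nuclear-marker level, the brightest rendered structure).
#'
#' @param image_size field side length in pixels.
#' @param pixel_size_um calibration; 0.2 um/px places the 2-5 um^2 area
#'   gates at 50-125 pixels per object.
#' @param n_nuclei number of non-overlapping nuclei to place.
#' @param nucleus_axes_um range of ellipse semi-axes in micrometres.
#' @param nucleus_marker_level nuclear-marker intensity inside nuclei.
#' @param second_marker_level second (nucleoplasmic) marker intensity.
#' @param n_nucleoli_range inclusive range of nucleoli per nucleus.
#' @param nucleolus_area_um2 range of nucleolus areas (um^2), sampled
#'   uniformly.
#' @param hole_depth fractional intensity drop of nucleoli in the marker
#'   channels (0-1); also the probe drop in `"depleted"` mode.
#' @param probe_mode `"enriched"` (nucleolar probe level =
#'   `enrichment x` nucleoplasmic level) or `"depleted"`
#'   (`(1 - hole_depth) x`).
#' @param enrichment nucleolar enrichment factor for `"enriched"` mode.
#' @param nucleoplasm_probe_level probe intensity in the nucleoplasm.
#' @param probe_effect multiplicative treatment effect applied to the
#'   nucleolar probe level (1 = untreated).
#' @param background_offset additive camera/staining background.
#' @param gradient linear background gradient `c(per_row, per_col)` in
#'   intensity units across the full field.
#' @param noise_sd_frac Gaussian noise sigma as a fraction of
#'   `nucleus_marker_level`.
#' @param noise_model `"gaussian"` or `"poisson"` (Poisson draws with the
#'   noise-free value as the mean, then adds the Gaussian floor).
#' @param jitter_pct within-nucleus nucleolar intensity jitter: each
#'   nucleolus's probe level is scaled by `N(1, jitter_pct/100)`.
#' @param bit_depth container depth for all channels.
#' @param seed RNG seed; identical parameters give bit-identical fields.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(image_size = 768L,
                         pixel_size_um = 0.2,
                         n_nuclei = 20L,
                         nucleus_axes_um = c(5.5, 7),
                         nucleus_marker_level = 20000,
                         second_marker_level = 16000,
                         n_nucleoli_range = c(2L, 3L),
                         nucleolus_area_um2 = c(2, 5),
                         hole_depth = 0.5,
                         probe_mode = c("enriched", "depleted"),
                         enrichment = 2,
                         nucleoplasm_probe_level = 10000,
                         probe_effect = 1,
                         background_offset = 2000,
                         gradient = c(0, 0),
                         noise_sd_frac = 0.02,
                         noise_model = c("gaussian", "poisson"),
                         jitter_pct = 10,
                         bit_depth = 16L,
                         seed = 20110603L) {
  probe_mode <- match.arg(probe_mode)
  noise_model <- match.arg(noise_model)
  stopifnot(image_size >= 32, pixel_size_um > 0, n_nuclei >= 0,
            hole_depth >= 0, hole_depth <= 1,
            diff(nucleolus_area_um2) >= 0, enrichment > 0,
            probe_effect > 0, noise_sd_frac >= 0, jitter_pct >= 0)
  p <- list(image_size = as.integer(image_size),
            pixel_size_um = pixel_size_um, n_nuclei = as.integer(n_nuclei),
            nucleus_axes_um = nucleus_axes_um,
            nucleus_marker_level = nucleus_marker_level,
            second_marker_level = second_marker_level,
            n_nucleoli_range = as.integer(n_nucleoli_range),
            nucleolus_area_um2 = nucleolus_area_um2,
            hole_depth = hole_depth, probe_mode = probe_mode,
            enrichment = enrichment,
            nucleoplasm_probe_level = nucleoplasm_probe_level,
            probe_effect = probe_effect,
            background_offset = background_offset, gradient = gradient,
            noise_sd_frac = noise_sd_frac, noise_model = noise_model,
            jitter_pct = jitter_pct, bit_depth = as.integer(bit_depth),
            seed = as.integer(seed))
  class(p) <- "synth_params"
  p
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multi-channel field with ground truth
#'
#' Renders non-overlapping elliptical nuclei containing disk-shaped
#' nucleoli, emits noise-free ground-truth masks and a per-nucleolus truth
#' table, then adds background, gradient and seeded noise to the three
#' channels. Nucleolar pixels in the marker channels are the marker level
#' times `(1 - hole_depth)`; in the probe channel they are the
#' nucleoplasmic level times the enrichment factor (enriched mode) or
#' `(1 - hole_depth)` (depleted mode), times the treatment effect and the
#' per-nucleolus jitter factor.
#'
#' @param p a [synth_params()].
#' @return List with `channels` (named list of [calibrated_image()]s:
#'   `nuclear_marker`, `second_marker`, `probe`) and `truth` (list with
#'   `nucleus_mask`, `nucleolus_mask`, `nucleoli` and `nuclei` truth
#'   tables, and `params`).
#' @export
generate_field <- function(p) {
  stopifnot(inherits(p, "synth_params"))
  with_seed(p$seed, generate_field_impl(p))
}

generate_field_impl <- function(p) {
  n <- p$image_size
  ps <- p$pixel_size_um
  ax_px <- p$nucleus_axes_um / ps

  # --- place non-overlapping elliptical nuclei -------------------------
  centers <- matrix(numeric(0), 0, 2)
  axes <- matrix(numeric(0), 0, 2)
  angles <- numeric(0)
  tries <- 0L
  while (nrow(centers) < p$n_nuclei) {
    tries <- tries + 1L
    if (tries > 5000L)
      stop("infeasible packing: cannot place ", p$n_nuclei,
           " nuclei in a ", n, "x", n, " field")
    a <- runif(1, ax_px[1], ax_px[2])
    b <- runif(1, ax_px[1], ax_px[2])
    th <- runif(1, 0, pi)
    rmax <- max(a, b) + 2
    if (rmax + 2 >= n - rmax - 2)
      stop("infeasible packing: nuclei of semi-axis ", round(rmax),
           " px do not fit in a ", n, "x", n, " field")
    cx <- runif(1, rmax + 2, n - rmax - 2)
    cy <- runif(1, rmax + 2, n - rmax - 2)
    ok <- TRUE
    if (nrow(centers)) {
      d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      prev_r <- pmax(axes[, 1], axes[, 2]) + 2
      ok <- all(d > rmax + prev_r + 2)
    }
    if (ok) {
      centers <- rbind(centers, c(cx, cy))
      axes <- rbind(axes, c(a, b))
      angles <- c(angles, th)
    }
  }

  row_idx <- matrix(rep(seq_len(n) - 1, n), n, n)        # 0-based rows
  col_idx <- matrix(rep(seq_len(n) - 1, each = n), n, n) # 0-based cols

  nucleus_mask <- matrix(0L, n, n)
  for (k in seq_len(p$n_nuclei)) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    a <- axes[k, 1]; b <- axes[k, 2]; th <- angles[k]
    r0 <- max(1L, floor(cx - max(a, b))); r1 <- min(n, ceiling(cx + max(a, b)))
    c0 <- max(1L, floor(cy - max(a, b))); c1 <- min(n, ceiling(cy + max(a, b)))
    rr <- row_idx[r0:r1, c0:c1] - cx
    cc <- col_idx[r0:r1, c0:c1] - cy
    u <- rr * cos(th) + cc * sin(th)
    v <- -rr * sin(th) + cc * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    sub <- nucleus_mask[r0:r1, c0:c1]
    sub[inside] <- k
    nucleus_mask[r0:r1, c0:c1] <- sub
  }

  # --- place nucleoli inside nuclei ------------------------------------
  nucleolus_mask <- matrix(0L, n, n)
  truth <- list()
  nid <- 0L
  for (k in seq_len(p$n_nuclei)) {
    n_no <- if (p$n_nucleoli_range[1] == p$n_nucleoli_range[2])
      p$n_nucleoli_range[1]
    else sample(seq(p$n_nucleoli_range[1], p$n_nucleoli_range[2]), 1L)
    cx <- centers[k, 1]; cy <- centers[k, 2]
    a <- axes[k, 1]; b <- axes[k, 2]; th <- angles[k]
    placed <- matrix(numeric(0), 0, 3)  # row, col, radius_px
    for (j in seq_len(n_no)) {
      area <- runif(1, p$nucleolus_area_um2[1], p$nucleolus_area_um2[2])
      r_px <- sqrt(area / pi) / ps
      for (t in seq_len(200L)) {
        # sample inside the ellipse, keep a margin so the disk fits
        uu <- runif(1, -1, 1); vv <- runif(1, -1, 1)
        if (uu^2 + vv^2 > 1) next
        margin <- (r_px + 2) / min(a, b)
        if (sqrt(uu^2 + vv^2) > max(0, 1 - margin)) next
        px <- cx + uu * a * cos(th) - vv * b * sin(th)
        py <- cy + uu * a * sin(th) + vv * b * cos(th)
        if (nrow(placed) &&
            any(sqrt((placed[, 1] - px)^2 + (placed[, 2] - py)^2) <
                placed[, 3] + r_px + 2)) next
        placed <- rbind(placed, c(px, py, r_px))
        nid <- nid + 1L
        r0 <- max(1L, floor(px - r_px)); r1 <- min(n, ceiling(px + r_px))
        c0 <- max(1L, floor(py - r_px)); c1 <- min(n, ceiling(py + r_px))
        rr <- row_idx[r0:r1, c0:c1] - px
        cc <- col_idx[r0:r1, c0:c1] - py
        inside <- rr^2 + cc^2 <= r_px^2
        sub <- nucleolus_mask[r0:r1, c0:c1]
        sub[inside] <- nid
        nucleolus_mask[r0:r1, c0:c1] <- sub
        truth[[nid]] <- c(nucleolus_id = nid, nucleus_id = k,
                          center_row = px, center_col = py,
                          radius_px = r_px)
        break
      }
    }
  }
  jitter <- if (nid > 0)
    pmax(rnorm(nid, 1, p$jitter_pct / 100), 0.05) else numeric(0)

  # --- render noise-free channels --------------------------------------
  in_nuc <- nucleus_mask > 0L
  in_nol <- nucleolus_mask > 0L
  marker <- matrix(0, n, n)
  marker[in_nuc] <- p$nucleus_marker_level
  marker[in_nol] <- p$nucleus_marker_level * (1 - p$hole_depth)
  marker2 <- matrix(0, n, n)
  marker2[in_nuc] <- p$second_marker_level
  marker2[in_nol] <- p$second_marker_level * (1 - p$hole_depth)
  nol_level <- if (p$probe_mode == "enriched")
    p$nucleoplasm_probe_level * p$enrichment * p$probe_effect
  else p$nucleoplasm_probe_level * (1 - p$hole_depth) * p$probe_effect
  probe <- matrix(0, n, n)
  probe[in_nuc] <- p$nucleoplasm_probe_level
  if (nid > 0) {
    lv <- nol_level * jitter[nucleolus_mask[in_nol]]
    probe[in_nol] <- lv
  }

  # --- truth tables (before background/noise) --------------------------
  if (nid > 0) {
    tt <- as.data.frame(do.call(rbind, truth))
    area_px <- tabulate(nucleolus_mask[in_nol], nbins = nid)
    tt$area_um2 <- area_px * ps^2
    tt$probe_level <- nol_level * jitter
    tt$mean_intensity <- tt$probe_level / ps^2
  } else {
    tt <- data.frame(nucleolus_id = integer(0), nucleus_id = integer(0),
                     center_row = numeric(0), center_col = numeric(0),
                     radius_px = numeric(0), area_um2 = numeric(0),
                     probe_level = numeric(0), mean_intensity = numeric(0))
  }
  nuc_area_px <- if (p$n_nuclei > 0)
    tabulate(nucleus_mask[in_nuc], nbins = p$n_nuclei) else integer(0)
  nt <- data.frame(nucleus_id = seq_len(p$n_nuclei),
                   center_row = centers[, 1], center_col = centers[, 2],
                   semi_axis_a_um = axes[, 1] * ps,
                   semi_axis_b_um = axes[, 2] * ps,
                   area_um2 = nuc_area_px * ps^2)

  # --- background, gradient, noise -------------------------------------
  grad <- p$gradient[1] * row_idx / max(n - 1, 1) +
          p$gradient[2] * col_idx / max(n - 1, 1)
  sd_noise <- p$noise_sd_frac * p$nucleus_marker_level
  finish <- function(m) {
    m <- m + p$background_offset + grad
    if (p$noise_model == "poisson") m <- matrix(rpois(n * n, m), n, n)
    if (sd_noise > 0) m <- m + rnorm(n * n, 0, sd_noise)
    m <- round(pmin(pmax(m, 0), 2^p$bit_depth - 1))
    m
  }
  channels <- list(
    nuclear_marker = calibrated_image(finish(marker), p$bit_depth,
                                      "nuclear_marker", ps),
    second_marker = calibrated_image(finish(marker2), p$bit_depth,
                                     "second_marker", ps),
    probe = calibrated_image(finish(probe), p$bit_depth, "probe", ps))

  list(channels = channels,
       truth = list(nucleus_mask = label_mask(nucleus_mask, ps),
                    nucleolus_mask = label_mask(nucleolus_mask, ps),
                    nucleoli = tt, nuclei = nt, params = p))
}

#' Generate a synthetic HTS plate
#'
#' Builds per-well, per-site fields with treatment-specific effect
#' multipliers applied to the nucleolar area range and the nucleolar probe
#' level, plus one cell-free background image sharing the field's offset,
#' gradient and noise model. Site seeds derive deterministically from the
#' base seed, so the whole plate is reproducible.
#'
#' @param layout a [plate_layout()].
#' @param effects named list, treatment -> `c(area = ..., intensity = ...)`
#'   multiplicative effects (vehicle wells use `c(1, 1)`).
#' @param p base [synth_params()] for every site.
#' @return List with `sites` (each `well`, `site`, `experiment`,
#'   `treatment`, `channels`, `truth`) and `background`
#'   ([calibrated_image()]).
#' @export
generate_plate <- function(layout, effects, p) {
  stopifnot(inherits(layout, "plate_layout"), inherits(p, "synth_params"))
  for (tr in unique(layout$wells$treatment)) {
    if (!tr %in% names(effects))
      stop("no effect multipliers for treatment: ", tr)
  }
  sites <- list()
  idx <- 0L
  for (w in seq_len(nrow(layout$wells))) {
    trt <- layout$wells$treatment[w]
    eff <- effects[[trt]]
    for (s in seq_len(layout$sites_per_well)) {
      idx <- idx + 1L
      ps_i <- p
      ps_i$nucleolus_area_um2 <- p$nucleolus_area_um2 * eff[["area"]]
      ps_i$probe_effect <- p$probe_effect * eff[["intensity"]]
      ps_i$seed <- (p$seed + idx * 7919L) %% 2147483647L
      f <- generate_field(ps_i)
      sites[[idx]] <- list(well = layout$wells$well[w], site = s,
                           experiment = layout$wells$experiment[w],
                           treatment = trt,
                           channels = f$channels, truth = f$truth)
    }
  }
  bg_p <- p
  bg_p$n_nuclei <- 0L
  bg_p$seed <- (p$seed + 104729L) %% 2147483647L
  bg <- generate_field(bg_p)
  background <- bg$channels$probe
  list(sites = sites, background = background)
}

#' Match detected nucleoli against ground truth
#'
#' Greedy one-to-one matching by pixel overlap (largest overlaps first); a
#' truth object counts as recovered when a detected segment covers at
#' least `min_overlap_frac` of it. Recall is matched truth objects over
#' all truth objects; precision is matched detections over all
#' detections.
#'
#' @param detected a [label_mask()] of detected segments.
#' @param truth a [label_mask()] of ground-truth objects.
#' @param min_overlap_frac minimum fraction of the truth object's pixels
#'   a detection must cover (default 0.3).
#' @return List with `recall`, `precision`, `n_truth`, `n_detected` and
#'   a `matches` data frame (`truth_label`, `detected_label`,
#'   `overlap_px`, `overlap_frac`).
#' @export
evaluate_detection <- function(detected, truth, min_overlap_frac = 0.3) {
  stopifnot(inherits(detected, "label_mask"), inherits(truth, "label_mask"))
  dt <- detected$labels; tr <- truth$labels
  check_same_geometry(list(pixels = dt), list(pixels = tr))
  n_truth <- max(tr); n_det <- max(dt)
  truth_sizes <- object_sizes(tr)
  sel <- dt > 0L & tr > 0L
  if (!any(sel) || n_truth == 0L || n_det == 0L) {
    return(list(recall = if (n_truth) 0 else NA_real_,
                precision = if (n_det) 0 else NA_real_,
                n_truth = n_truth, n_detected = n_det,
                matches = data.frame(truth_label = integer(0),
                                     detected_label = integer(0),
                                     overlap_px = integer(0),
                                     overlap_frac = numeric(0))))
  }
  ov <- as.data.frame(table(truth_label = tr[sel], detected_label = dt[sel]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0L, ]
  ov$truth_label <- as.integer(ov$truth_label)
  ov$detected_label <- as.integer(ov$detected_label)
  ov$overlap_frac <- ov$Freq / truth_sizes[ov$truth_label]
  ov <- ov[ov$overlap_frac >= min_overlap_frac, ]
  ov <- ov[order(-ov$Freq, ov$truth_label, ov$detected_label), ]
  used_t <- logical(n_truth); used_d <- logical(n_det)
  keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    t_i <- ov$truth_label[i]; d_i <- ov$detected_label[i]
    if (!used_t[t_i] && !used_d[d_i]) {
      keep[i] <- TRUE
      used_t[t_i] <- TRUE; used_d[d_i] <- TRUE
    }
  }
  m <- ov[keep, c("truth_label", "detected_label", "Freq", "overlap_frac")]
  names(m)[3] <- "overlap_px"
  rownames(m) <- NULL
  list(recall = nrow(m) / n_truth, precision = nrow(m) / n_det,
       n_truth = n_truth, n_detected = n_det, matches = m)
}
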