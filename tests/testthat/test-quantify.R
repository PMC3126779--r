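make_scene <- function(nol, nuc, parent_of, ps = 0.2) {
  structure(list(nucleolus_mask = label_mask(nol, ps),
                 nucleus_mask = label_mask(nuc, ps),
                 parent_of = stats::setNames(as.integer(parent_of),
                                             seq_along(parent_of))),
            class = "scene_segmentation")
}

test_that("measure_objects computes the arithmetic contract", {
  # uniform segment of 10 px at value 100, 0.2 um pixels
  nol <- matrix(0L, 10, 10); nol[2, 1:10] <- 1L
  nuc <- matrix(1L, 10, 10)
  px <- matrix(100, 10, 10)
  probe <- calibrated_image(px, 16, "probe", 0.2)
  m <- measure_objects(probe, make_scene(nol, nuc, 1L))
  expect_equal(m$nucleoli$area_um2, 0.4)
  expect_equal(m$nucleoli$integrated_intensity, 1000)
  expect_equal(m$nucleoli$mean_intensity, 2500)
  # nucleus sums mirror the member nucleolus
  expect_equal(m$nuclei$nucleolar_sum_intensity, 1000)
  expect_equal(m$nuclei$nucleolar_sum_area, 0.4)
  expect_equal(m$nuclei$nuclear_integrated_intensity, 100 * 100)
})

test_that("empty segmentation gives empty tables", {
  probe <- calibrated_image(matrix(0, 5, 5), 8, "probe", 0.2)
  m <- measure_objects(probe, make_scene(matrix(0L, 5, 5), matrix(0L, 5, 5),
                                         integer(0)))
  expect_equal(nrow(m$nucleoli), 0L)
  expect_equal(nrow(m$nuclei), 0L)
})

test_that("per-nucleus statistics combine member nucleoli correctly", {
  # two equal-area nucleoli of means a and b -> per-nucleus value (a+b)/2
  nol <- matrix(0L, 10, 10); nol[1, 1:5] <- 1L; nol[5, 1:5] <- 2L
  nuc <- matrix(1L, 10, 10)
  px <- matrix(0, 10, 10); px[1, 1:5] <- 80; px[5, 1:5] <- 120
  m <- measure_objects(calibrated_image(px, 16, "probe", 0.2),
                       make_scene(nol, nuc, c(1L, 1L)))
  a <- m$nucleoli$mean_intensity[1]; b <- m$nucleoli$mean_intensity[2]
  expect_equal(m$nuclei$per_nucleus_mean, (a + b) / 2)
  # conservation: per-nucleus sums equal sums over members (exact)
  expect_identical(m$nuclei$nucleolar_sum_intensity,
                   sum(m$nucleoli$integrated_intensity))
  # single-nucleolus nucleus: per-nucleus value equals that mean
  m1 <- measure_objects(calibrated_image(px, 16, "probe", 0.2),
                        make_scene((nol == 1L) * 1L, nuc, 1L))
  expect_equal(m1$nuclei$per_nucleus_mean, m1$nucleoli$mean_intensity[1])
})

test_that("nucleolar/nuclear ratio obeys its limiting identities", {
  nuc <- matrix(0L, 12, 12); nuc[3:10, 3:10] <- 1L
  nol <- matrix(0L, 12, 12); nol[5:6, 5:6] <- 1L
  # probe entirely inside nucleoli -> ratio 1
  px <- matrix(0, 12, 12); px[5:6, 5:6] <- 500
  m <- measure_objects(calibrated_image(px, 16, "probe", 0.2),
                       make_scene(nol, nuc, 1L))
  expect_equal(nucleolar_nuclear_ratio(m$nuclei)$ratio, 1)
  # uniform probe -> ratio = nucleolar area / nuclear area
  pu <- matrix(0, 12, 12); pu[nuc == 1L] <- 300
  mu <- measure_objects(calibrated_image(pu, 16, "probe", 0.2),
                        make_scene(nol, nuc, 1L))
  expect_equal(nucleolar_nuclear_ratio(mu$nuclei)$ratio, 4 / 64)
  # zero nuclear intensity flags the row
  mz <- measure_objects(calibrated_image(matrix(0, 12, 12), 16, "probe", 0.2),
                        make_scene(nol, nuc, 1L))
  r <- nucleolar_nuclear_ratio(mz$nuclei)
  expect_true(r$flagged)
  expect_true(is.na(r$ratio))
})

test_that("enrichment ratio matches the closed form on generator output", {
  p <- synth_params(noise_sd_frac = 0, jitter_pct = 0, seed = 55)
  f <- generate_field(p)
  corrected <- statistical_correction(f$channels$probe, roi = corner_roi())
  scene <- make_scene(f$truth$nucleolus_mask$labels,
                      f$truth$nucleus_mask$labels,
                      f$truth$nucleoli$nucleus_id)
  r <- nucleolar_nuclear_ratio(measure_objects(corrected, scene)$nuclei)
  # closed form e*A_no / (e*A_no + A_np) per nucleus, from truth geometry
  e <- p$enrichment
  nuc_area <- f$truth$nuclei$area_um2
  agg <- tapply(f$truth$nucleoli$area_um2, f$truth$nucleoli$nucleus_id, sum)
  A_no <- rep(0, nrow(f$truth$nuclei))
  A_no[as.integer(names(agg))] <- as.numeric(agg)
  closed <- e * A_no / (e * A_no + (nuc_area - A_no))
  expect_true(all(abs(r$ratio - closed) / closed < 0.05))
})

test_that("within-nucleus variability matches hand computation", {
  rec <- data.frame(nucleus_id = c(1L, 1L, 2L, 2L, 3L),
                    mean_intensity = c(90, 110, 50, 50, 7))
  out <- within_nucleus_variability(rec)
  # {90,110}: sd = 14.142..., mean 100 -> 14.14%; {50,50}: 0%; single skipped
  expect_equal(out$n_nuclei, 2L)
  expect_equal(out$stdev_pct, (100 * sd(c(90, 110)) / 100 + 0) / 2)
  expect_equal(100 * sd(c(90, 110)) / 100, 14.14214, tolerance = 1e-6)
})

test_that("generated within-nucleus jitter is recovered", {
  p <- synth_params(n_nucleoli_range = c(3L, 3L), jitter_pct = 12,
                    noise_sd_frac = 0.005, seed = 66)
  f <- generate_field(p)
  res <- run_method(f$channels, segmentation_params(method_id = 1),
                    list(roi = corner_roi()))
  out <- within_nucleus_variability(res$nucleoli)
  # CV of N(1, 0.12) truncated at 0.05: close to 12%; allow sampling error
  expect_gt(out$stdev_pct, 7)
  expect_lt(out$stdev_pct, 17)
})

test_that("histograms share edges across conditions and conserve counts", {
  v <- c(1, 2, 2.5, 3, 4, 4)
  cond <- c("a", "a", "a", "b", "b", "b")
  h <- histogram_counts(v, cond, breaks = c(1, 2, 3, 4))
  expect_equal(dim(h$counts), c(3L, 2L))
  expect_equal(sum(h$counts), length(v))
  # values on edges go to the right-open bin; the top edge is included
  expect_equal(unname(h$counts[, "a"]), c(1L, 2L, 0L))   # 2 -> [2,3)
  expect_equal(unname(h$counts[, "b"]), c(0L, 0L, 3L))   # 3 -> [3,4]; 4 kept
  expect_error(histogram_counts(numeric(0)), "empty")
  # automatic equal-width bins are identical for every condition
  h2 <- histogram_counts(v, cond, breaks = 4)
  expect_equal(length(h2$breaks), 5L)
  expect_equal(sum(h2$counts), 6L)
})

test_that("compare_groups reproduces the hand-computed pooled t", {
  cmp <- compare_groups(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cmp$statistic, bf_pooled_t(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(cmp$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(cmp$p, 0.2878641, tolerance = 1e-6)
  # identical groups: t = 0, p = 1
  cmp0 <- compare_groups(c(5, 5, 5), c(5, 5, 5))
  expect_equal(cmp0$statistic, 0)
  expect_equal(cmp0$p, 1)
  # three identical groups: ANOVA F = 0
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_equal(compare_groups(groups = g)$statistic, 0)
  expect_error(compare_groups(c(1, 2), c(3)), ">= 2 values")
})

test_that("condition summaries normalize control to exactly 1", {
  rec <- data.frame(mean_intensity = c(1, 2, 3, 2, 3, 4),
                    condition = rep(c("ctrl", "hs"), each = 3))
  s <- per_nucleolus_analysis(rec, control = "ctrl")
  expect_equal(s$normalized_mean[s$condition == "ctrl"], 1)
  expect_equal(s$normalized_mean[s$condition == "hs"], 3 / 2)
  expect_equal(s$statistic[s$condition == "hs"],
               bf_pooled_t(c(2, 3, 4), c(1, 2, 3)))
  # two identical conditions: both normalized 1, p = 1
  rec2 <- data.frame(mean_intensity = rep(c(1, 2, 3), 2),
                     condition = rep(c("ctrl", "same"), each = 3))
  s2 <- per_nucleolus_analysis(rec2, control = "ctrl")
  expect_equal(s2$normalized_mean, c(1, 1))
  expect_equal(s2$p_value[2], 1, tolerance = 1e-12)
  expect_error(per_nucleolus_analysis(rec, control = "nope"), "unknown")
})

test_that("intensity statistics scale with the probe; ratios do not", {
  nol <- matrix(0L, 10, 10); nol[2:3, 2:3] <- 1L; nol[7:8, 7:8] <- 2L
  nuc <- matrix(1L, 10, 10)
  set.seed(9)
  px <- matrix(sample(50:150, 100, TRUE), 10, 10)
  scene <- make_scene(nol, nuc, c(1L, 1L))
  m1 <- measure_objects(calibrated_image(px, 16, "probe", 0.2), scene)
  k <- 3
  m2 <- measure_objects(calibrated_image(px * k, 16, "probe", 0.2), scene)
  expect_equal(m2$nucleoli$integrated_intensity,
               k * m1$nucleoli$integrated_intensity)
  expect_equal(m2$nucleoli$mean_intensity, k * m1$nucleoli$mean_intensity)
  expect_equal(nucleolar_nuclear_ratio(m2$nuclei)$ratio,
               nucleolar_nuclear_ratio(m1$nuclei)$ratio)
})
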