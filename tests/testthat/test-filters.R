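test_that("dark-hole response matches the hand-computed toy raster", {
  px <- matrix(100, 15, 15)
  px[7:9, 7:9] <- 40
  img <- calibrated_image(px, 8, "nuclear_marker", 0.2)
  r <- detect_dark_holes(img, structuring_element(9))
  expect_equal(r$pixels[7:9, 7:9], matrix(60, 3, 3))
  expect_equal(r$pixels[1:3, 1:3], matrix(0, 3, 3))
  # flat field gives an all-zero response
  flat <- calibrated_image(matrix(77, 12, 12), 8, "nuclear_marker", 0.2)
  expect_true(all(detect_dark_holes(flat, structuring_element(5))$pixels == 0))
  expect_true(all(detect_light_holes(flat, structuring_element(5))$pixels == 0))
})

test_that("light-hole response matches the hand-computed bright block", {
  px <- matrix(100, 15, 15)
  px[7:9, 7:9] <- 160
  img <- calibrated_image(px, 8, "probe", 0.2)
  r <- detect_light_holes(img, structuring_element(9))
  expect_equal(r$pixels[8, 8], 60)
  expect_equal(r$pixels[1, 1], 0)
})

test_that("hole responses agree with brute-force morphology oracles", {
  set.seed(21)
  for (rep in 1:20) {
    px <- matrix(sample(0:255, 15 * 15, TRUE), 15, 15)
    img <- calibrated_image(px, 8, "probe", 0.2)
    se <- structuring_element(sample(c(3, 5, 7), 1))
    expect_equal(detect_dark_holes(img, se)$pixels,
                 bf_bottom_hat(px, se$footprint))
    expect_equal(detect_light_holes(img, se)$pixels,
                 bf_top_hat(px, se$footprint))
  }
})

test_that("light holes are the dual of dark holes under inversion", {
  set.seed(31)
  for (rep in 1:10) {
    px <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    se <- structuring_element(5)
    a <- detect_light_holes(calibrated_image(px, 8, "probe", 0.2), se)$pixels
    b <- detect_dark_holes(calibrated_image(255 - px, 8, "probe", 0.2),
                           se)$pixels
    expect_equal(a, b)
  }
})

test_that("bottom-hat response is monotone in hole depth", {
  base <- matrix(200, 21, 21)
  se <- structuring_element(9)
  shallow <- base; shallow[10:12, 10:12] <- 170   # depth 30
  deep <- base; deep[10:12, 10:12] <- 140         # depth 60
  rs <- detect_dark_holes(calibrated_image(shallow, 8, "probe", 0.2), se)
  rd <- detect_dark_holes(calibrated_image(deep, 8, "probe", 0.2), se)
  expect_gte(max(rd$pixels), max(rs$pixels))
  # pointwise deepening never decreases the response anywhere
  expect_true(all(rd$pixels >= rs$pixels))
})

test_that("add_images sums, saturates and enhances hole contrast", {
  a <- calibrated_image(matrix(40000, 4, 4), 16, "nuclear_marker", 0.2)
  z <- calibrated_image(matrix(0, 4, 4), 16, "second_marker", 0.2)
  expect_equal(add_images(a, z)$pixels, a$pixels)      # identity
  expect_equal(add_images(a, a)$pixels, matrix(65535, 4, 4))  # saturation
  expect_equal(add_images(a, z)$bit_depth, 16L)
  expect_error(add_images(a, calibrated_image(matrix(0, 5, 4), 16,
                                              "probe", 0.2)), "shape")
  # nucleolus/nucleoplasm contrast of the sum >= either input's contrast
  f <- generate_field(synth_params(seed = 91, noise_sd_frac = 0))
  s <- add_images(f$channels$nuclear_marker, f$channels$second_marker)
  no <- f$truth$nucleolus_mask$labels > 0
  np <- f$truth$nucleus_mask$labels > 0 & !no
  contrast <- function(px) abs(mean(px[np]) - mean(px[no]))
  expect_gte(contrast(s$pixels), contrast(f$channels$nuclear_marker$pixels))
  expect_gte(contrast(s$pixels), contrast(f$channels$second_marker$pixels))
})

test_that("median filter matches the brute-force sliding median", {
  set.seed(41)
  for (rep in 1:12) {
    nr <- sample(6:14, 1); nc <- sample(6:14, 1)
    px <- matrix(sample(0:4095, nr * nc, TRUE), nr, nc)
    w <- sample(c(1, 3, 5), 1); h <- sample(c(1, 3, 5), 1)
    out <- median_filter(calibrated_image(px, 12, "probe", 0.2),
                         median_params(w, h))
    expect_equal(out$pixels, bf_median(px, w, h))
  }
})

test_that("median filter restores a salt pixel and keeps flat fields", {
  px <- matrix(10, 7, 7); px[4, 4] <- 255
  out <- median_filter(calibrated_image(px, 8, "probe", 0.2),
                       median_params(3, 3))
  expect_equal(out$pixels[4, 4], 10)
  flat <- calibrated_image(matrix(99, 9, 9), 8, "probe", 0.2)
  expect_equal(median_filter(flat, median_params(5, 5))$pixels,
               flat$pixels)
})

test_that("median sub-sampling evaluates a strided grid with nearest fill", {
  set.seed(5)
  px <- matrix(sample(0:255, 12 * 12, TRUE), 12, 12)
  out <- median_filter(calibrated_image(px, 8, "probe", 0.2),
                       median_params(3, 3, subsample_ratio = 3))
  full <- bf_median(px, 3, 3)
  # evaluated pixels (0-based rows/cols 0,3,6,9) carry the true median
  for (i in c(1, 4, 7, 10)) for (j in c(1, 4, 7, 10))
    expect_equal(out$pixels[i, j], full[i, j])
  # a non-evaluated pixel copies its nearest evaluated pixel
  expect_equal(out$pixels[2, 2], full[1, 1])
  expect_equal(out$pixels[3, 3], full[4, 4])
})

test_that("erode and dilate follow classical binary morphology", {
  ps <- 0.2
  se <- structuring_element(6)
  single <- matrix(FALSE, 15, 15); single[8, 8] <- TRUE
  m <- binary_mask(single, ps)
  expect_true(all(!erode(m, se)$pixels))       # single pixel vanishes
  d <- dilate(m, se)$pixels                    # grows to the disk footprint
  expect_equal(sum(d), sum(se$footprint))
  expect_equal(unname(d[5:11, 5:11]), unname(se$footprint))
  full <- binary_mask(matrix(TRUE, 10, 10), ps)
  expect_true(all(erode(full, se)$pixels))     # white padding at borders
  empty <- binary_mask(matrix(FALSE, 10, 10), ps)
  expect_true(all(!dilate(empty, se)$pixels))
})

test_that("erode/dilate satisfy duality and opening anti-extensivity", {
  set.seed(61)
  for (rep in 1:15) {
    px <- matrix(runif(20 * 20) > 0.6, 20, 20)
    m <- binary_mask(px, 0.2)
    se <- structuring_element(sample(3:6, 1))
    # duality: dilate(x) == !erode(!x)
    inv <- binary_mask(!px, 0.2)
    expect_equal(dilate(m, se)$pixels, !erode(inv, se)$pixels)
    # oracle equivalence
    expect_equal(erode(m, se)$pixels,
                 matrix(bf_erode(px, se$footprint), 20, 20))
    expect_equal(dilate(m, se)$pixels,
                 matrix(bf_dilate(px, se$footprint), 20, 20))
    # opening is anti-extensive: erode-then-dilate contained in original
    opened <- dilate(erode(m, se), se)$pixels
    expect_true(all(px[opened]))
  }
})

test_that("statistical correction subtracts the background mean and clamps", {
  img <- calibrated_image(matrix(50, 8, 8), 8, "probe", 0.2)
  out <- statistical_correction(img, roi = c(0, 0, 7, 7))
  expect_true(all(out$pixels == 0))            # constant image -> zeros
  # pixel 5 with background mean 10 -> 0
  px <- matrix(5, 4, 4); px[1, 1] <- 10
  img2 <- calibrated_image(px, 8, "probe", 0.2)
  bg <- calibrated_image(matrix(10, 4, 4), 8, "probe", 0.2)
  out2 <- statistical_correction(img2, background = bg)
  expect_equal(out2$pixels[2, 2], 0)
  expect_error(statistical_correction(img, roi = c(0, 0, 3, 3),
                                      background = bg), "exactly one")
  expect_error(statistical_correction(img, roi = c(2, 2, 1, 1)), "empty ROI")
})

test_that("a known constant offset is exactly recovered via a cell-free ROI", {
  p <- synth_params(image_size = 256L, n_nuclei = 2L, noise_sd_frac = 0,
                    background_offset = 1500, seed = 77)
  f <- generate_field(p)
  # pick a corner 16x16 block that the truth marks as cell-free
  nuc <- f$truth$nucleus_mask$labels
  corners <- list(c(0, 0), c(0, 240), c(240, 0), c(240, 240))
  free <- Filter(function(cr) all(nuc[cr[1] + 1:16, cr[2] + 1:16] == 0),
                 corners)[[1]]
  roi <- c(free[1], free[2], free[1] + 15, free[2] + 15)
  corrected <- statistical_correction(f$channels$probe, roi = roi)
  truth_probe <- f$channels$probe$pixels - 1500
  expect_equal(corrected$pixels, pmax(truth_probe, 0))
})
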