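# Shared fixtures, built once per session and memoized. All synthetic data
# derive from the generator with fixed seeds printed in the parameter
# objects themselves.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_field <- function() fixture("default_field", function() {
  generate_field(synth_params())
})

corner_roi <- function() c(0, 0, 30, 30)

method1_result <- function() fixture("method1_result", function() {
  f <- default_field()
  run_method(f$channels, segmentation_params(method_id = 1),
             list(roi = corner_roi()))
})

method1_erode_dilate_result <- function() {
  fixture("method1_ed_result", function() {
    f <- default_field()
    run_method(f$channels,
               segmentation_params(method_id = 1,
                                   noise_filter = "erode_dilate"),
               list(roi = corner_roi()))
  })
}

# small flat-nucleus scene with hand-placed holes, used for unit tests
toy_scene <- function(hole_areas_um2 = c(3, 3), depth = 0.5, ps = 0.2,
                      size = 101L, level = 20000) {
  px <- matrix(0, size, size)
  cx <- (size + 1) / 2
  rr <- matrix(rep(seq_len(size), size), size, size) - cx
  cc <- t(rr)
  nucleus <- rr^2 + cc^2 <= (size / 2 - 4)^2
  px[nucleus] <- level
  centers <- list(c(-12, 0), c(12, 0), c(0, -18), c(0, 18))
  truth <- matrix(0L, size, size)
  for (k in seq_along(hole_areas_um2)) {
    r_px <- sqrt(hole_areas_um2[k] / pi) / ps
    d2 <- (rr - centers[[k]][1])^2 + (cc - centers[[k]][2])^2
    hole <- d2 <= r_px^2
    px[hole] <- level * (1 - depth)
    truth[hole] <- k
  }
  list(img = calibrated_image(px, 16, "nuclear_marker", ps),
       truth = label_mask(truth, ps),
       nucleus = label_mask(matrix(as.integer(nucleus), size, size), ps))
}
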