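# Independent brute-force reference implementations used to validate the
# compiled morphology kernels. Deliberately written as plain R loops over
# window definitions, sharing no code with the package internals.

bf_median <- function(m, width, height) {
  nr <- nrow(m); nc <- ncol(m)
  hr <- height %/% 2; hc <- width %/% 2
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      rs <- max(1, i - hr):min(nr, i + hr)
      cs <- max(1, j - hc):min(nc, j + hc)
      out[i, j] <- stats::median(m[rs, cs])
    }
  }
  out
}

# grayscale erosion/dilation with footprint fp (odd-sided logical matrix);
# out-of-bounds neighbours ignored (neutral padding)
bf_gray <- function(m, fp, op) {
  nr <- nrow(m); nc <- ncol(m)
  cr <- (nrow(fp) + 1) %/% 2; ccn <- (ncol(fp) + 1) %/% 2
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (a in seq_len(nrow(fp))) {
        for (b in seq_len(ncol(fp))) {
          if (!fp[a, b]) next
          ii <- i + a - cr; jj <- j + b - ccn
          if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
          vals <- c(vals, m[ii, jj])
        }
      }
      out[i, j] <- op(vals)
    }
  }
  out
}

bf_erode <- function(mask, fp) bf_gray(mask, fp, min) > 0.5
bf_dilate <- function(mask, fp) bf_gray(mask, fp, max) > 0.5
bf_closing <- function(m, fp) bf_gray(bf_gray(m, fp, max), fp, min)
bf_opening <- function(m, fp) bf_gray(bf_gray(m, fp, min), fp, max)
bf_bottom_hat <- function(m, fp) pmax(bf_closing(m, fp) - m, 0)
bf_top_hat <- function(m, fp) pmax(m - bf_opening(m, fp), 0)

# pooled-variance two-sample t statistic, hand formula
bf_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}
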