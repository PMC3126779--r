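#' Write a QC overlay PNG
#'
#' Renders the image as grayscale with nucleus outlines in green and
#' nucleolus segment outlines in red, for spot-checking that segments
#' colocalize with the dark holes. Batch scoring never gates on this
#' output; it exists for optional visual verification only.
#'
#' @param img a [calibrated_image()] shown underneath.
#' @param seg a `scene_segmentation` (see [run_method()]).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(img, seg, path) {
  stopifnot(inherits(img, "calibrated_image"))
  px <- img$pixels
  g <- px / max(px, 1)
  outline <- function(labels) {
    up <- rbind(labels[-1, , drop = FALSE], labels[nrow(labels), ])
    dn <- rbind(labels[1, ], labels[-nrow(labels), , drop = FALSE])
    lf <- cbind(labels[, -1, drop = FALSE], labels[, ncol(labels)])
    rt <- cbind(labels[, 1], labels[, -ncol(labels), drop = FALSE])
    labels > 0L & (up != labels | dn != labels | lf != labels | rt != labels)
  }
  r <- g; gg <- g; b <- g
  nuc_edge <- outline(seg$nucleus_mask$labels)
  nol_edge <- outline(seg$nucleolus_mask$labels)
  r[nuc_edge] <- 0; gg[nuc_edge] <- 1; b[nuc_edge] <- 0
  r[nol_edge] <- 1; gg[nol_edge] <- 0; b[nol_edge] <- 0
  png::writePNG(array(c(r, gg, b), dim = c(nrow(g), ncol(g), 3)), path)
  invisible(path)
}
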