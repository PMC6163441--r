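# Separable bicubic resampling (Catmull-Rom-type kernel, a = -0.5), the
# standard kernel of image toolboxes. When downscaling, the kernel is
# widened by 1/scale (antialiasing). Out-of-range source indices are
# clamped to the edge. Weights are renormalized to sum to 1, so constant
# images are preserved exactly.

bicubic_kernel <- function(x) {
  a <- -0.5
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

#' @noRd
scaled_dim <- function(n, scale) max(1L, as.integer(round(n * scale)))

# n_out x n_in row-stochastic interpolation matrix for one axis.
resize_weights <- function(n_in, scale) {
  n_out <- scaled_dim(n_in, scale)
  kscale <- if (scale < 1) scale else 1
  support <- 2 / kscale
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    u <- (i - 0.5) / scale - 0.5      # 0-based source center
    lo <- floor(u - support) ; hi <- ceiling(u + support)
    idx <- lo:hi
    wts <- bicubic_kernel((u - idx) * kscale)
    keep <- wts != 0
    idx <- idx[keep]; wts <- wts[keep]
    idx <- pmin(pmax(idx, 0), n_in - 1)  # clamp (edge replicate)
    for (k in seq_along(idx)) W[i, idx[k] + 1] <- W[i, idx[k] + 1] + wts[k]
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Resize an image by bicubic interpolation
#'
#' @param image Matrix or h x w x 3 array in \[0, 255\].
#' @param scale Scale factor in (0, 1\]; the working images are produced at
#'   40\% of the captured resolution.
#' @return Resized image, rounded back to 8-bit integers in \[0, 255\].
#' @export
resize_bicubic <- function(image, scale) {
  stopifnot(scale > 0, scale <= 1)
  validate_image(image)
  one <- function(m, Wr, Wc) Wr %*% m %*% t(Wc)
  if (is.matrix(image)) {
    Wr <- resize_weights(nrow(image), scale)
    Wc <- resize_weights(ncol(image), scale)
    out <- one(image, Wr, Wc)
  } else {
    Wr <- resize_weights(dim(image)[1], scale)
    Wc <- resize_weights(dim(image)[2], scale)
    out <- array(0, c(nrow(Wr), nrow(Wc), 3))
    for (ch in 1:3) out[, , ch] <- one(image[, , ch], Wr, Wc)
  }
  out <- round(out)
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Downscale a mask with nearest-neighbor sampling
#'
#' Used to bring a full-resolution ground-truth mask to the working
#' resolution while preserving binarity. Output dimensions follow the same
#' rule as [resize_bicubic()].
#'
#' @param mask Binary mask over \{0, 255\}.
#' @param scale Scale factor in (0, 1\].
#' @return Binary mask at the scaled size.
#' @export
resize_mask_nearest <- function(mask, scale) {
  validate_mask(mask)
  h <- scaled_dim(nrow(mask), scale)
  w <- scaled_dim(ncol(mask), scale)
  ri <- pmin(pmax(floor((seq_len(h) - 0.5) / scale - 0.5 + 0.5), 0),
             nrow(mask) - 1) + 1
  ci <- pmin(pmax(floor((seq_len(w) - 0.5) / scale - 0.5 + 0.5), 0),
             ncol(mask) - 1) + 1
  mask[ri, ci, drop = FALSE]
}
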