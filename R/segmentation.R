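# The segmentation algorithm: preprocessing (downscale + Gaussian smoothing,
# RGB -> HSV), fusion of the saturation channel with the inverted value
# channel, background estimation by grayscale opening and subtraction,
# Otsu binarization, then binary opening and hole filling.

#' Segmentation configuration
#'
#' Bundles the tunable parameters of the segmentation pipeline. Defaults are
#' the published settings: 40\% bicubic downscale, 5x5 Gaussian of sigma 0.8,
#' a 50 px disk for background estimation (large enough to contain any
#' olive at working resolution) and a 3 px disk for mask cleanup.
#'
#' @param scale_factor Downscale factor in (0, 1].
#' @param gaussian_sigma Gaussian standard deviation in pixels (> 0).
#' @param gaussian_kernel Odd kernel size >= 3.
#' @param bg_disk_radius Disk radius (px) for background opening.
#' @param clean_disk_radius Disk radius (px) for binary opening of the mask.
#' @param wide_range If `TRUE`, the saturation + inverted-value fusion keeps
#'   the full 0-510 range and the background-subtracted image is linearly
#'   rescaled to 0-255 before Otsu, instead of saturating 8-bit arithmetic.
#' @param min_contrast Minimum peak value (gray levels) the high-contrast
#'   image must reach for the scene to be considered to contain fruit at
#'   all. Otsu's method always proposes a split, even of a fruit-free mat
#'   where the background-subtracted image is only quantization noise and a
#'   few levels of fold relief; requiring 10 levels of contrast (about 4\%
#'   of the dynamic range, comfortably above that floor and far below the
#'   ~200-level contrast of real fruit) makes such scenes come back as an
#'   empty mask with a warning. Set to 0 to disable the guard.
#' @return Object of class `seg_config`.
#' @export
seg_config <- function(scale_factor = 0.40, gaussian_sigma = 0.8,
                       gaussian_kernel = 5L, bg_disk_radius = 50L,
                       clean_disk_radius = 3L, wide_range = FALSE,
                       min_contrast = 10) {
  stopifnot(scale_factor > 0, scale_factor <= 1,
            gaussian_sigma > 0,
            gaussian_kernel >= 3, gaussian_kernel %% 2 == 1,
            bg_disk_radius >= 1, clean_disk_radius >= 1,
            min_contrast >= 0)
  structure(list(scale_factor = scale_factor,
                 gaussian_sigma = gaussian_sigma,
                 gaussian_kernel = as.integer(gaussian_kernel),
                 bg_disk_radius = as.integer(bg_disk_radius),
                 clean_disk_radius = as.integer(clean_disk_radius),
                 wide_range = isTRUE(wide_range),
                 min_contrast = min_contrast),
            class = "seg_config")
}

#' @export
print.seg_config <- function(x, ...) {
  cat("segmentation config:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Truncated rotationally symmetric Gaussian, renormalized to sum 1.
gaussian_kernel_2d <- function(size, sigma) {
  half <- (size - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- outer(g1, g1)
  k / sum(k)
}

# 2D convolution of a single channel with reflect (symmetric) padding.
convolve_reflect <- function(m, kernel) {
  half <- (nrow(kernel) - 1) / 2
  h <- nrow(m); w <- ncol(m)
  reflect <- function(i, n) {   # symmetric, edge-inclusive
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n + 1 - i, i)
    }
    i
  }
  out <- matrix(0, h, w)
  for (dr in -half:half) {
    ri <- reflect(seq_len(h) + dr, h)
    for (dc in -half:half) {
      ci <- reflect(seq_len(w) + dc, w)
      out <- out + kernel[dr + half + 1, dc + half + 1] * m[ri, ci]
    }
  }
  out
}

#' Gaussian smoothing of one channel
#'
#' Convolution with the truncated rotationally symmetric Gaussian
#' (renormalized to sum 1), reflect padding at the borders.
#'
#' @param m Single-channel matrix.
#' @param sigma Standard deviation in pixels.
#' @param size Odd kernel size.
#' @return Smoothed matrix (not rounded).
#' @export
gaussian_smooth <- function(m, sigma = 0.8, size = 5L) {
  stopifnot(is.matrix(m), sigma > 0, size %% 2 == 1)
  convolve_reflect(m, gaussian_kernel_2d(size, sigma))
}

#' Preprocess a captured image
#'
#' Bicubic downscale to the working resolution, then per-channel Gaussian
#' smoothing against salt-and-pepper noise; output rounded to 8-bit.
#'
#' @param image h x w x 3 RGB array in \[0, 255\].
#' @param config A [seg_config()].
#' @return RGB array at the working resolution.
#' @export
preprocess <- function(image, config = seg_config()) {
  validate_image(image, channels = 3)
  small <- resize_bicubic(image, config$scale_factor)
  out <- small
  for (ch in 1:3) {
    out[, , ch] <- gaussian_smooth(small[, , ch], config$gaussian_sigma,
                                   config$gaussian_kernel)
  }
  out <- round(out)
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Split an RGB image into saturation and value channels
#'
#' Standard hexcone HSV: V = max(R,G,B); S = 0 where V = 0, otherwise
#' (V - min(R,G,B)) / V. Both channels are rescaled to \[0, 255\] and
#' rounded to the nearest integer so the later 8-bit arithmetic is coherent.
#'
#' @param image h x w x 3 RGB array in \[0, 255\].
#' @return List with matrices `S` and `V`.
#' @export
split_hsv <- function(image) {
  validate_image(image, channels = 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  hsv <- grDevices::rgb2hsv(rbind(as.vector(image[, , 1]),
                                  as.vector(image[, , 2]),
                                  as.vector(image[, , 3])),
                            maxColorValue = 255)
  list(S = matrix(round(hsv["s", ] * 255), h, w),
       V = matrix(round(hsv["v", ] * 255), h, w))
}

#' Invert a value channel
#'
#' Per-pixel 255 - V, so fruits (dark) become the brightest structures.
#'
#' @param V Single-channel matrix in \[0, 255\].
#' @return Inverted channel.
#' @export
invert_value <- function(V) {
  validate_image(V, channels = 1)
  255 - V
}

#' Fuse saturation with the inverted value channel
#'
#' Per-pixel S + V_inv. By default the sum saturates at 255 (8-bit
#' arithmetic); with `wide_range = TRUE` the full 0-510 range is kept for
#' later rescaling.
#'
#' @param S Saturation channel in \[0, 255\].
#' @param V_inv Inverted value channel, same shape.
#' @param wide_range Keep the unclipped sum?
#' @return Fused channel.
#' @export
fuse_channels <- function(S, V_inv, wide_range = FALSE) {
  if (!identical(dim(S), dim(V_inv))) {
    stop("S and V_inv must have identical shape", call. = FALSE)
  }
  out <- S + V_inv
  if (!wide_range) out[out > 255] <- 255
  out
}

#' Estimate the scene background by grayscale opening
#'
#' Opening with a disk large enough to contain any fruit removes the fruits
#' but keeps the smooth brightness folds of the mat; the result is an
#' estimate of the background, pixelwise <= the input.
#'
#' @param I_SV Fused channel.
#' @param radius Disk radius in pixels.
#' @return Background estimate, same shape.
#' @export
estimate_background <- function(I_SV, radius = 50L) {
  stopifnot(is.matrix(I_SV))
  gray_open(I_SV, radius)
}

#' Subtract the background estimate
#'
#' Per-pixel max(I_SV - I_bg, 0): the high-contrast image to be binarized.
#'
#' @param I_SV Fused channel.
#' @param I_bg Background estimate, same shape.
#' @return High-contrast channel, floored at 0.
#' @export
subtract_background <- function(I_SV, I_bg) {
  if (!identical(dim(I_SV), dim(I_bg))) {
    stop("I_SV and I_bg must have identical shape", call. = FALSE)
  }
  out <- I_SV - I_bg
  out[out < 0] <- 0
  out
}

#' Otsu's threshold of an 8-bit channel
#'
#' Exhaustively maximizes the between-class variance over the 256-bin
#' integer histogram; ties are broken by the smallest threshold. The
#' returned t is meant for strict `> t` binarization, so t = 255 is never
#' returned.
#'
#' @param I Single-channel matrix with values in \[0, 255\].
#' @return Integer threshold in \[0, 254\].
#' @export
otsu_threshold <- function(I) {
  v <- as.integer(round(as.vector(I)))
  if (any(v < 0 | v > 255)) stop("channel values must lie in [0, 255]",
                                 call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  if (sum(counts > 0) < 2) {
    stop("degenerate histogram: all pixels share one intensity",
         call. = FALSE)
  }
  p <- counts / sum(counts)
  levels <- 0:255
  omega <- cumsum(p)                    # weight of class {0..t}
  mu <- cumsum(p * levels)              # unnormalized class-0 mean
  mu_total <- mu[256]
  t_all <- 0:254
  w0 <- omega[t_all + 1]
  m0 <- mu[t_all + 1]
  sigma_b <- (mu_total * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[w0 == 0 | w0 == 1] <- -Inf
  as.integer(t_all[which.max(sigma_b)])
}

#' Binarize a channel at a threshold
#'
#' Strict inequality: pixels > t become 255, all others 0.
#'
#' @param I Single-channel matrix.
#' @param t Threshold in \[0, 255\].
#' @return Binary mask over \{0, 255\}.
#' @export
binarize <- function(I, t) {
  stopifnot(t >= 0, t <= 255)
  out <- matrix(0, nrow(I), ncol(I))
  out[I > t] <- 255
  out
}

#' Remove small false-positive components
#'
#' Binary opening with a small disk: connected components too small to be
#' fruits are eliminated; real fruit outlines are barely affected.
#'
#' @param mask Binary mask.
#' @param radius Disk radius in pixels (default 3).
#' @return Cleaned mask, foreground a subset of the input's.
#' @export
clean_mask <- function(mask, radius = 3L) {
  binary_open(mask, radius)
}

#' Fill interior holes of a mask
#'
#' Morphological reconstruction by erosion from a border-valued marker:
#' every background region not 4-connected to the image border (e.g. the
#' specular-highlight holes inside fruits) becomes foreground. Foreground is
#' never removed, and the operation is idempotent.
#'
#' @param mask Binary mask.
#' @return Mask with interior holes filled.
#' @export
fill_holes <- function(mask) {
  validate_mask(mask)
  out <- cpp_fill_holes(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  matrix(as.numeric(out), nrow(mask), ncol(mask))
}

#' Segment fruits in a captured RGB image
#'
#' Full pipeline: preprocess, HSV split, value inversion, channel fusion,
#' background opening and subtraction, Otsu binarization, binary opening,
#' hole filling. The returned mask is at the working (downscaled)
#' resolution; its Otsu threshold is attached as attribute
#' `otsu_threshold`.
#'
#' If the high-contrast image is degenerate — a single occupied histogram
#' bin, or peak contrast below `config$min_contrast` as on a fruit-free
#' mat — an empty mask is returned with a warning.
#'
#' @param image h x w x 3 RGB array in \[0, 255\].
#' @param config A [seg_config()].
#' @return Binary mask at working resolution.
#' @export
segment <- function(image, config = seg_config()) {
  pre <- preprocess(image, config)
  sv <- split_hsv(pre)
  v_inv <- invert_value(sv$V)
  i_sv <- fuse_channels(sv$S, v_inv, wide_range = config$wide_range)
  i_bg <- estimate_background(i_sv, config$bg_disk_radius)
  i_hc <- subtract_background(i_sv, i_bg)
  if (max(i_hc) < config$min_contrast) {
    warning(sprintf(
      "high-contrast image is degenerate (peak contrast %g < %g); treating scene as fruit-free",
      max(i_hc), config$min_contrast), call. = FALSE)
    mask <- matrix(0, nrow(i_hc), ncol(i_hc))
    attr(mask, "otsu_threshold") <- NA_integer_
    return(mask)
  }
  if (config$wide_range) {
    rng <- max(i_hc)
    i_hc <- if (rng > 0) round(i_hc / rng * 255) else i_hc
  }
  t <- tryCatch(otsu_threshold(i_hc), error = function(e) NULL)
  if (is.null(t)) {
    warning("degenerate histogram in high-contrast image; returning empty mask",
            call. = FALSE)
    mask <- matrix(0, nrow(i_hc), ncol(i_hc))
    attr(mask, "otsu_threshold") <- NA_integer_
    return(mask)
  }
  mask <- binarize(i_hc, t)
  mask <- clean_mask(mask, config$clean_disk_radius)
  mask <- fill_holes(mask)
  attr(mask, "otsu_threshold") <- t
  mask
}
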