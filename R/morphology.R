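# Grayscale and binary morphology with a Euclidean discrete disk
# {(dr,dc): dr^2 + dc^2 <= r^2}. Out-of-image neighbors are taken by
# symmetric (edge-inclusive) reflection, as for all filters in the package.

#' Grayscale erosion with a disk structuring element
#'
#' @param img Single-channel matrix.
#' @param radius Disk radius in pixels (>= 1).
#' @return Matrix of the same shape.
#' @export
gray_erode <- function(img, radius) {
  stopifnot(is.matrix(img), radius >= 1)
  cpp_gray_morph(img, as.integer(radius), FALSE)
}

#' Grayscale dilation with a disk structuring element
#'
#' @inheritParams gray_erode
#' @return Matrix of the same shape.
#' @export
gray_dilate <- function(img, radius) {
  stopifnot(is.matrix(img), radius >= 1)
  cpp_gray_morph(img, as.integer(radius), TRUE)
}

#' Grayscale opening (erosion then dilation)
#'
#' Anti-extensive: the result never exceeds the input. With a disk large
#' enough to contain every fruit it estimates the mat background.
#'
#' @inheritParams gray_erode
#' @return Matrix of the same shape, pixelwise <= `img`.
#' @export
gray_open <- function(img, radius) {
  gray_dilate(gray_erode(img, radius), radius)
}

#' Binary opening of a mask
#'
#' Removes foreground structures smaller than the disk; used to discard
#' connected components too small to be fruits.
#'
#' @param mask Binary mask over \{0, 255\}.
#' @param radius Disk radius in pixels.
#' @return Binary mask, foreground a subset of the input's.
#' @export
binary_open <- function(mask, radius) {
  validate_mask(mask)
  out <- gray_open(mask, radius)
  out[out != 0] <- 255
  out
}
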