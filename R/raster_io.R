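# Raster containers are plain base-R objects: a single-channel image is an
# h x w numeric matrix of integers in [0, 255]; an RGB image is an h x w x 3
# array on the same scale; a binary mask is an h x w matrix over {0, 255}.
# Coordinates are 0-based (row, col), origin top-left, row-major.

#' Validate an 8-bit raster image
#'
#' Checks that `x` is an h x w matrix (single channel) or h x w x 3 array
#' (RGB) with all intensities in \[0, 255\].
#'
#' @param x Matrix or 3-slice array.
#' @param channels Required channel count (1, 3, or NULL for either).
#' @return `x`, invisibly. Errors on violation.
#' @export
validate_image <- function(x, channels = NULL) {
  ok1 <- is.matrix(x) && is.numeric(x)
  ok3 <- is.array(x) && !is.matrix(x) && length(dim(x)) == 3 && dim(x)[3] == 3
  if (!ok1 && !ok3) {
    stop("image must be an h x w numeric matrix or an h x w x 3 array",
         call. = FALSE)
  }
  nch <- if (ok1) 1L else 3L
  if (!is.null(channels) && nch != channels) {
    stop(sprintf("image must have %d channel(s), got %d", channels, nch),
         call. = FALSE)
  }
  if (nrow(x) < 1 || ncol(x) < 1) stop("image has empty extent", call. = FALSE)
  rng <- range(x)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop("image intensities must lie in [0, 255] and contain no NA",
         call. = FALSE)
  }
  invisible(x)
}

#' Validate a binary mask
#'
#' A mask is an h x w matrix whose values are exactly 0 (background) or
#' 255 (foreground = fruit).
#'
#' @param x Matrix to check.
#' @return `x`, invisibly. Errors on violation.
#' @export
validate_mask <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("mask must be a numeric matrix", call. = FALSE)
  }
  if (!all(x == 0 | x == 255)) {
    stop("mask values must all be 0 or 255", call. = FALSE)
  }
  invisible(x)
}

#' Read an image file
#'
#' Decodes an 8-bit PNG or JPEG into a matrix (grayscale) or h x w x 3
#' array (RGB) of integers in \[0, 255\]. An alpha channel, if present,
#' is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return Numeric matrix or h x w x 3 array on the 0-255 scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      stop(sprintf("unsupported image format '%s' for '%s'", ext, path),
           call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("failed to decode image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  x <- round(raw * 255)
  if (length(dim(x)) == 3) {
    if (dim(x)[3] == 1) x <- x[, , 1] else x <- x[, , 1:3, drop = FALSE]
  }
  validate_image(x)
  x
}

#' Write a binary mask as a lossless PNG
#'
#' @param mask Binary mask matrix over \{0, 255\}.
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  validate_mask(mask)
  ok <- tryCatch({
    png::writePNG(mask / 255, target = path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("failed to write mask to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' Hand-painted ground truths may contain stray intermediate values; any
#' nonzero pixel is normalized to 255 on read.
#'
#' @param path Path to a PNG mask.
#' @return Mask matrix over \{0, 255\}.
#' @export
read_mask <- function(path) {
  x <- read_image(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x[x != 0] <- 255
  validate_mask(x)
  x
}

#' Write an RGB image as PNG
#'
#' @param image h x w x 3 array on the 0-255 scale.
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  validate_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Read a reference measurement table
#'
#' Loads the caliper/balance reference CSV: one row per fruit with its
#' physical axis lengths (mm), mass (g) and approximate image position
#' (0-based row/col of the fruit center).
#'
#' @param path CSV with columns `image_id`, `fruit_id`, `major_axis_mm`,
#'   `minor_axis_mm`, `mass_g`, `pos_row`, `pos_col`.
#' @return `data.frame` with those columns, validated.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read reference table: no such file '%s'", path),
         call. = FALSE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_reference_table(df)
}

#' Validate a reference table
#'
#' @param df Data frame in the reference-table schema.
#' @return `df`, with rows in input order, or an error listing offending rows.
#' @export
validate_reference_table <- function(df) {
  required <- c("image_id", "fruit_id", "major_axis_mm", "minor_axis_mm",
                "mass_g", "pos_row", "pos_col")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("reference table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!(df$major_axis_mm >= df$minor_axis_mm) |
                 !(df$minor_axis_mm > 0) | !(df$mass_g > 0))
  if (length(bad)) {
    stop(sprintf(
      "reference table rows violate major >= minor > 0 and mass > 0: %s",
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  key <- paste(df$image_id, df$fruit_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop(sprintf("duplicate (image_id, fruit_id) in reference table rows: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  df
}
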