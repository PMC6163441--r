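# Per-fruit descriptors from a binary mask: 8-connected component labeling,
# pixel area, centroid, and ellipse axes from the normalized second central
# moments of the component's pixel coordinates.

#' Label connected components (8-connectivity)
#'
#' Foreground pixels touching horizontally, vertically or diagonally belong
#' to the same component. Labels start at 1 and are assigned in row-major
#' order of each component's first pixel, so labeling is deterministic.
#'
#' @param mask Binary mask over \{0, 255\}.
#' @return List with `labels` (integer matrix, 0 = background) and `n`
#'   (component count).
#' @export
label_components <- function(mask) {
  validate_mask(mask)
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(mask), ncol(mask)))
  list(labels = lab, n = attr(lab, "n"))
}

#' Ellipse axes from second central moments
#'
#' Computes the ellipse having the same normalized second central moments as
#' the pixel set. Each pixel is treated as a unit square, adding 1/12 to both
#' diagonal entries of the coordinate covariance; with eigenvalues
#' lambda1 >= lambda2, the full axis lengths are 4*sqrt(lambda) — the unique
#' scale for which a filled continuous ellipse returns its true axes.
#' Orientation is the angle between the major axis and the column (x) axis,
#' counterclockwise with y pointing up, in (-pi/2, pi/2].
#'
#' @param rows,cols 0-based pixel coordinates of one component.
#' @return Named numeric vector: `major_axis_px`, `minor_axis_px`,
#'   `orientation` (radians).
#' @export
ellipse_axes <- function(rows, cols) {
  n <- length(rows)
  stopifnot(n >= 1, length(cols) == n)
  rbar <- mean(rows); cbar <- mean(cols)
  crr <- sum((rows - rbar)^2) / n + 1 / 12
  ccc <- sum((cols - cbar)^2) / n + 1 / 12
  crc <- sum((rows - rbar) * (cols - cbar)) / n
  # eigenvalues of [[ccc, crc], [crc, crr]]
  tr <- ccc + crr
  d <- sqrt((ccc - crr)^2 + 4 * crc^2)
  l1 <- (tr + d) / 2
  l2 <- (tr - d) / 2
  # math coords: x = col, y = -row => cov(x, y) = -crc
  theta <- 0.5 * atan2(-2 * crc, ccc - crr)
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  c(major_axis_px = 4 * sqrt(l1), minor_axis_px = 4 * sqrt(max(l2, 0)),
    orientation = theta)
}

#' Measure all components of a mask
#'
#' One record per 8-connected component: pixel area, centroid (0-based
#' fractional row/col) and moment-ellipse axes/orientation.
#'
#' @param mask Binary mask.
#' @param image_id Identifier recorded in the table.
#' @return `data.frame` with columns `image_id`, `label`, `area_px`,
#'   `centroid_row`, `centroid_col`, `major_axis_px`, `minor_axis_px`,
#'   `orientation_rad`. Empty masks give an empty table.
#' @export
measure_components <- function(mask, image_id = "image") {
  lc <- label_components(mask)
  empty <- data.frame(image_id = character(), label = integer(),
                      area_px = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), major_axis_px = numeric(),
                      minor_axis_px = numeric(), orientation_rad = numeric(),
                      stringsAsFactors = FALSE)
  if (lc$n == 0) return(empty)
  fg <- which(lc$labels != 0)
  rows0 <- (fg - 1) %% nrow(mask)          # 0-based
  cols0 <- (fg - 1) %/% nrow(mask)
  labs <- lc$labels[fg]
  recs <- lapply(seq_len(lc$n), function(k) {
    sel <- labs == k
    ax <- ellipse_axes(rows0[sel], cols0[sel])
    data.frame(image_id = image_id, label = k, area_px = sum(sel),
               centroid_row = mean(rows0[sel]), centroid_col = mean(cols0[sel]),
               major_axis_px = unname(ax["major_axis_px"]),
               minor_axis_px = unname(ax["minor_axis_px"]),
               orientation_rad = unname(ax["orientation"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Match measured components to reference fruits by position
#'
#' Greedy nearest-centroid pairing: candidate (component, reference) pairs
#' within `gate` pixels are taken in order of increasing distance, each side
#' used at most once. Two references tied at equal distance to the same
#' component is an error. Unmatched entries on either side are reported,
#' never silently dropped.
#'
#' The published method only records that measurements were associated to
#' fruit positions; this gate-matched nearest-centroid rule is this
#' package's explicit stand-in for the unspecified pairing procedure.
#'
#' @param components Component table from [measure_components()] (centroids
#'   in the same coordinate frame/resolution as the reference positions).
#' @param reference Reference table (columns `pos_row`, `pos_col`,
#'   `fruit_id`, ...) for the same image.
#' @param gate Maximum centroid-to-position distance in pixels; default
#'   1.5 x the median minor axis of the components.
#' @return List: `pairs` (data.frame joining component and reference
#'   columns plus `match_dist_px`), `unmatched_components` (labels),
#'   `unmatched_reference` (fruit_ids).
#' @export
match_to_reference <- function(components, reference,
                               gate = 1.5 * median(components$minor_axis_px)) {
  nc <- nrow(components); nr <- nrow(reference)
  if (nc == 0 || nr == 0) {
    return(list(pairs = NULL,
                unmatched_components = components$label,
                unmatched_reference = reference$fruit_id))
  }
  d <- outer(components$centroid_row, reference$pos_row, "-")^2 +
       outer(components$centroid_col, reference$pos_col, "-")^2
  d <- sqrt(d)
  cand <- which(d <= gate, arr.ind = TRUE)
  if (nrow(cand)) {
    dist <- d[cand]
    ord <- order(dist, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    dist <- dist[ord]
  } else {
    dist <- numeric()
  }
  used_c <- logical(nc); used_r <- logical(nr)
  pc <- integer(); pr <- integer(); pd <- numeric()
  i <- 1
  while (i <= nrow(cand)) {
    ci <- cand[i, 1]; ri <- cand[i, 2]
    if (!used_c[ci] && !used_r[ri]) {
      tie <- which(!used_r & abs(d[ci, ] - dist[i]) < 1e-9)
      if (length(tie) > 1) {
        stop(sprintf(
          "ambiguous match: references %s are equidistant (%.3f px) from component %d",
          paste(reference$fruit_id[tie], collapse = ", "), dist[i],
          components$label[ci]), call. = FALSE)
      }
      used_c[ci] <- TRUE; used_r[ri] <- TRUE
      pc <- c(pc, ci); pr <- c(pr, ri); pd <- c(pd, dist[i])
    }
    i <- i + 1
  }
  pairs <- NULL
  if (length(pc)) {
    pairs <- cbind(components[pc, , drop = FALSE],
                   reference[pr, setdiff(names(reference), "image_id"),
                             drop = FALSE],
                   match_dist_px = pd)
    rownames(pairs) <- NULL
  }
  list(pairs = pairs,
       unmatched_components = components$label[!used_c],
       unmatched_reference = reference$fruit_id[!used_r])
}
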