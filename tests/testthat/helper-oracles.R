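# Independent brute-force oracles, deliberately written with none of the
# package's shortcuts: direct per-pixel scans and exhaustive searches.

# symmetric (edge-inclusive) reflection, 1-based
reflect1 <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

disk_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, ]
}

# brute-force grayscale erosion/dilation with Euclidean disk + reflection
oracle_morph <- function(img, radius, dilate = FALSE) {
  offs <- disk_offsets(radius)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      vals <- numeric(nrow(offs))
      for (k in seq_len(nrow(offs))) {
        vals[k] <- img[reflect1(i + offs$dr[k], h), reflect1(j + offs$dc[k], w)]
      }
      out[i, j] <- if (dilate) max(vals) else min(vals)
    }
  }
  out
}

oracle_open <- function(img, radius) {
  oracle_morph(oracle_morph(img, radius, dilate = FALSE), radius, dilate = TRUE)
}

# exhaustive Otsu: between-class variance computed directly from the pixel
# populations for every candidate threshold 0..254; smallest argmax
oracle_otsu <- function(I) {
  v <- as.vector(I)
  n <- length(v)
  best_t <- NA_integer_; best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / n; w1 <- length(hi) / n
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t
}

# BFS connected-component count/labels, 8-connectivity, row-major first pixel
oracle_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextl <- 0L
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (mask[i, j] == 0 || lab[i, j] != 0) next
      nextl <- nextl + 1L
      queue <- list(c(i, j)); lab[i, j] <- nextl
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          qi <- p[1] + di; qj <- p[2] + dj
          if (qi >= 1 && qi <= h && qj >= 1 && qj <= w &&
              mask[qi, qj] != 0 && lab[qi, qj] == 0) {
            lab[qi, qj] <- nextl
            queue[[length(queue) + 1]] <- c(qi, qj)
          }
        }
      }
    }
  }
  list(labels = lab, n = nextl)
}

# reconstruction by erosion from a border-valued marker, iterated with a
# unit (4-neighbor cross) structuring element until idempotence
oracle_fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  marker <- matrix(255, h, w)
  border <- rbind(cbind(1, seq_len(w)), cbind(h, seq_len(w)),
                  cbind(seq_len(h), 1), cbind(seq_len(h), w))
  marker[border] <- mask[border]
  erode_cross <- function(m) {
    up <- rbind(m[1, ], m[-h, ]); down <- rbind(m[-1, ], m[h, ])
    left <- cbind(m[, 1], m[, -w]); right <- cbind(m[, -1], m[, w])
    pmin(m, up, down, left, right)
  }
  repeat {
    nxt <- pmax(erode_cross(marker), mask)
    if (identical(nxt, marker)) return(marker)
    marker <- nxt
  }
}

# filled rotated ellipse mask; theta: angle of the major axis from the
# column axis, counterclockwise with y up; 0-based center (r0, c0)
make_ellipse_mask <- function(h, w, r0, c0, a, b, theta = 0) {
  rows <- matrix(0:(h - 1), h, w)
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  dx <- cols - c0; dy <- -(rows - r0)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  out <- matrix(0, h, w)
  out[(u / a)^2 + (v / b)^2 <= 1] <- 255
  out
}

# deterministic random mask / channel fixtures
random_mask <- function(h, w, p = 0.3, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(ifelse(runif(h * w) < p, 255, 0), h, w)
}

random_channel <- function(h, w, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# small valid reference table
ref_fixture <- function() {
  data.frame(image_id = "img1", fruit_id = 1:3,
             major_axis_mm = c(20, 18, 22), minor_axis_mm = c(14, 12, 15),
             mass_g = c(2.5, 2.0, 3.0),
             pos_row = c(10, 40, 80), pos_col = c(10, 50, 90),
             stringsAsFactors = FALSE)
}
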