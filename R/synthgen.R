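# Seeded generator of synthetic conveyor-mat scenes with exact per-fruit
# ground truth: a bright weakly-saturated mat with low-frequency brightness
# folds, darker saturated elliptical fruits of two color families, cast
# shadows (darker but near-background saturation: shadowing scales all RGB
# channels equally, which lowers V and preserves hexcone S exactly), and
# small bright specular highlights inside the fruits.

#' Synthetic scene parameters
#'
#' Defaults emulate a laboratory conveyor-mat capture: a 720 x 960 px view
#' at 0.25 mm/px, ten well-separated olives with major axes of 14-24 mm and
#' minor axes of 10-18 mm (covering small and large table-olive cultivars),
#' modest mat folds and shadows, mild sensor noise, and a mass affine in the
#' projected ellipse area at about 0.011 g/mm^2 over a 0.2 g offset.
#'
#' @param image_size Integer (rows, cols) of the rendered image.
#' @param n_fruits Number of fruits.
#' @param mm_per_px Physical scale of the rendering.
#' @param major_mm_range,minor_mm_range Axis-length ranges in mm (minor is
#'   clipped to the sampled major).
#' @param color_family `"dark-purple"`, `"green-brown"` or `"mixed"`.
#' @param background_level Mat brightness (0-255).
#' @param fold_amplitude Amplitude (intensity units) of the low-frequency
#'   mat folds; 0 disables them.
#' @param shadow_strength Fractional darkening of cast shadows in \[0, 1).
#' @param highlight_count_per_fruit Specular blobs per fruit.
#' @param min_separation_px Minimum pairwise center distance; centers are
#'   additionally kept at least the sum of the semi-major axes + 6 px apart
#'   so fruits never touch.
#' @param noise_sigma Gaussian pixel-noise standard deviation.
#' @param mass_c1,mass_c0,mass_noise_sigma_g Mass law: `mass_g =
#'   c1 * (pi/4 * major_mm * minor_mm) + c0 + N(0, sigma_g)`.
#' @param volume_law If `TRUE`, mass is instead proportional to
#'   major * minor^2 (an ellipsoid-volume law, rescaled to comparable
#'   magnitudes), to probe how far a calibration linear in projected area
#'   degrades when the true law is volumetric.
#' @param seed Integer seed; scenes are bit-reproducible given the seed.
#' @param max_attempts Rejection-sampling cap for fruit placement.
#' @return Object of class `scene_params`.
#' @export
scene_params <- function(image_size = c(720L, 960L), n_fruits = 10L,
                         mm_per_px = 0.25,
                         major_mm_range = c(14, 24),
                         minor_mm_range = c(10, 18),
                         color_family = c("mixed", "dark-purple", "green-brown"),
                         background_level = 232,
                         fold_amplitude = 10,
                         shadow_strength = 0.25,
                         highlight_count_per_fruit = 2L,
                         min_separation_px = 130,
                         noise_sigma = 2,
                         mass_c1 = 0.011, mass_c0 = 0.2,
                         mass_noise_sigma_g = 0.08,
                         volume_law = FALSE,
                         seed = 0L, max_attempts = 10000L) {
  color_family <- match.arg(color_family)
  stopifnot(length(image_size) == 2, all(image_size >= 64),
            n_fruits >= 0, mm_per_px > 0,
            major_mm_range[1] > 0, diff(major_mm_range) >= 0,
            minor_mm_range[1] > 0, diff(minor_mm_range) >= 0,
            min_separation_px >= 0,
            shadow_strength >= 0, shadow_strength < 1,
            noise_sigma >= 0, mass_noise_sigma_g >= 0)
  structure(list(image_size = as.integer(image_size), n_fruits = as.integer(n_fruits),
                 mm_per_px = mm_per_px, major_mm_range = major_mm_range,
                 minor_mm_range = minor_mm_range, color_family = color_family,
                 background_level = background_level,
                 fold_amplitude = fold_amplitude,
                 shadow_strength = shadow_strength,
                 highlight_count_per_fruit = as.integer(highlight_count_per_fruit),
                 min_separation_px = min_separation_px,
                 noise_sigma = noise_sigma,
                 mass_c1 = mass_c1, mass_c0 = mass_c0,
                 mass_noise_sigma_g = mass_noise_sigma_g,
                 volume_law = isTRUE(volume_law),
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "scene_params")
}

# Pixel set of a filled rotated ellipse; returns 1-based matrix indices.
# theta follows the package orientation convention (x = col, y = -row).
ellipse_pixels <- function(h, w, r0, c0, semi_major, semi_minor, theta) {
  rr <- max(semi_major, semi_minor)
  rows <- max(1, floor(r0 - rr + 1)):min(h, ceiling(r0 + rr + 1))
  cols <- max(1, floor(c0 - rr + 1)):min(w, ceiling(c0 + rr + 1))
  dy <- -(rows - 1 - r0)              # math y, rows are 1-based
  dx <- cols - 1 - c0
  u <- outer(dy * sin(theta), dx * cos(theta), "+")   # along major axis
  v <- outer(dy * cos(theta), -dx * sin(theta), "+")  # along minor axis
  inside <- (u / semi_major)^2 + (v / semi_minor)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(rows[idx[, 1]], cols[idx[, 2]])
}

#' Generate one synthetic conveyor-mat scene
#'
#' Renders an RGB image and its exact ground truth. Fruit centers are
#' rejection-sampled under the separation constraint; a placement failure
#' after `max_attempts` draws is an error, never a silent shortfall.
#'
#' @param params A [scene_params()].
#' @return List with `image` (h x w x 3 array, 0-255), `mask` (binary
#'   ground-truth mask at the rendered resolution) and `fruits`
#'   (data.frame: fruit_id, center_row, center_col (0-based px),
#'   major_axis_mm, minor_axis_mm, orientation_rad, painted_area_px,
#'   mass_g).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)
  h <- params$image_size[1]; w <- params$image_size[2]
  bg <- params$background_level

  # mat: near-achromatic bright field with low-frequency brightness folds
  base <- c(bg, bg, bg - 6)
  fold <- matrix(0, h, w)
  if (params$fold_amplitude > 0) {
    rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (k in 1:3) {
      ang <- runif(1, 0, pi)
      # folds are wide relative to any fruit: half-wavelength comfortably
      # exceeds the background structuring disk at working resolution
      wav <- runif(1, 1.0, 2.0) * min(h, w)
      phase <- runif(1, 0, 2 * pi)
      fold <- fold + sin(2 * pi * (rr * cos(ang) + cc * sin(ang)) / wav + phase)
    }
    fold <- params$fold_amplitude * fold / 3
  }
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- base[ch] + fold

  # fruit geometry
  n <- params$n_fruits
  maj_mm <- runif(n, params$major_mm_range[1], params$major_mm_range[2])
  min_mm <- pmin(runif(n, params$minor_mm_range[1], params$minor_mm_range[2]),
                 maj_mm)
  theta <- runif(n, -pi / 2, pi / 2)
  semi_a <- maj_mm / 2 / params$mm_per_px   # semi-major, px
  semi_b <- min_mm / 2 / params$mm_per_px
  shadow_off <- pmax(3, 0.3 * semi_b)

  centers <- matrix(NA_real_, n, 2)
  attempts <- 0L
  for (k in seq_len(n)) {
    margin <- semi_a[k] + shadow_off[k] + 4
    placed <- FALSE
    while (!placed) {
      attempts <- attempts + 1L
      if (attempts > params$max_attempts) {
        stop(sprintf(
          "could not place %d fruits under the separation constraint after %d attempts",
          n, params$max_attempts), call. = FALSE)
      }
      cand <- c(runif(1, margin, h - 1 - margin), runif(1, margin, w - 1 - margin))
      ok <- TRUE
      if (k > 1) {
        for (j in seq_len(k - 1)) {
          dmin <- max(params$min_separation_px, semi_a[k] + semi_a[j] + 6)
          if (sqrt(sum((cand - centers[j, ])^2)) < dmin) { ok <- FALSE; break }
        }
      }
      if (ok) { centers[k, ] <- cand; placed <- TRUE }
    }
  }

  families <- switch(params$color_family,
    "dark-purple" = rep("dark-purple", n),
    "green-brown" = rep("green-brown", n),
    "mixed" = sample(c("dark-purple", "green-brown"), n, replace = TRUE))
  base_cols <- list("dark-purple" = c(62, 30, 70),
                    "green-brown" = c(105, 110, 50))

  mask <- matrix(0, h, w)
  area_px <- integer(n)
  fruit_px <- vector("list", n)
  for (k in seq_len(n)) {
    fruit_px[[k]] <- ellipse_pixels(h, w, centers[k, 1], centers[k, 2],
                                    semi_a[k], semi_b[k], theta[k])
    area_px[k] <- nrow(fruit_px[[k]])
  }

  # shadows first (fruit pixels overwrite them): equal scaling of all
  # channels keeps saturation at the background's, only value drops
  if (params$shadow_strength > 0) {
    for (k in seq_len(n)) {
      sp <- ellipse_pixels(h, w,
                           centers[k, 1] + shadow_off[k],
                           centers[k, 2] + shadow_off[k],
                           semi_a[k], semi_b[k], theta[k])
      for (ch in 1:3) {
        idx <- cbind(sp, ch)
        img[idx] <- img[idx] * (1 - params$shadow_strength)
      }
    }
  }

  for (k in seq_len(n)) {
    col <- base_cols[[families[k]]] + runif(3, -12, 12)
    px <- fruit_px[[k]]
    for (ch in 1:3) img[cbind(px, ch)] <- col[ch]
    mask[px] <- 255
    # specular highlights: small bright near-achromatic blobs inside
    for (hl in seq_len(params$highlight_count_per_fruit)) {
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.45)
      hr <- centers[k, 1] - rad * semi_b[k] * sin(ang)
      hc <- centers[k, 2] + rad * semi_a[k] * cos(ang)
      hrad <- runif(1, 2, 4.5)
      hp <- ellipse_pixels(h, w, hr, hc, hrad, hrad, 0)
      hcol <- c(241, 241, 238) + runif(3, -4, 4)
      for (ch in 1:3) img[cbind(hp, ch)] <- hcol[ch]
    }
  }

  if (params$noise_sigma > 0) {
    img <- img + array(rnorm(h * w * 3, 0, params$noise_sigma), c(h, w, 3))
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255

  ellipse_area_mm2 <- pi / 4 * maj_mm * min_mm
  if (params$volume_law) {
    # ellipsoid-volume law rescaled to the magnitude of the area law
    vol <- pi / 6 * maj_mm * min_mm^2
    x <- vol * 1.5 / mean(params$minor_mm_range)
  } else {
    x <- ellipse_area_mm2
  }
  mass <- params$mass_c1 * x + params$mass_c0
  if (params$mass_noise_sigma_g > 0) {
    mass <- mass + rnorm(n, 0, params$mass_noise_sigma_g)
  }
  mass <- pmax(mass, 0.01)

  fruits <- data.frame(fruit_id = seq_len(n),
                       center_row = centers[, 1], center_col = centers[, 2],
                       major_axis_mm = maj_mm, minor_axis_mm = min_mm,
                       orientation_rad = theta,
                       painted_area_px = area_px,
                       mass_g = mass,
                       color_family = families,
                       stringsAsFactors = FALSE)
  list(image = img, mask = mask, fruits = fruits)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` scenes (PNG image + PNG ground-truth mask each), a
#' reference CSV in the reference-table schema and a JSON manifest with the
#' exact parameters, so the dataset can be regenerated bit-identically.
#' Scene i uses seed `params$seed + i - 1`.
#'
#' @param n_images Number of scenes.
#' @param params A [scene_params()]; per-scene seeds are derived from
#'   `params$seed`.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list with `params`, `images`, `masks`,
#'   `reference`).
#' @export
generate_dataset <- function(n_images, params = scene_params(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  imgs <- character(n_images); msks <- character(n_images)
  refs <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    p <- params
    p$seed <- params$seed + i - 1L
    sc <- generate_scene(p)
    id <- sprintf("scene_%03d", i)
    imgs[i] <- file.path(out_dir, paste0(id, ".png"))
    msks[i] <- file.path(out_dir, paste0(id, "_truth.png"))
    write_image(sc$image, imgs[i])
    write_mask(sc$mask, msks[i])
    refs[[i]] <- data.frame(image_id = id, fruit_id = sc$fruits$fruit_id,
                            major_axis_mm = sc$fruits$major_axis_mm,
                            minor_axis_mm = sc$fruits$minor_axis_mm,
                            mass_g = sc$fruits$mass_g,
                            pos_row = sc$fruits$center_row,
                            pos_col = sc$fruits$center_col,
                            painted_area_px = sc$fruits$painted_area_px,
                            stringsAsFactors = FALSE)
  }
  ref <- do.call(rbind, refs)
  ref_path <- file.path(out_dir, "reference.csv")
  write.csv(ref, ref_path, row.names = FALSE)
  manifest <- list(params = unclass(params), n_images = n_images,
                   images = basename(imgs), masks = basename(msks),
                   reference = basename(ref_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
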