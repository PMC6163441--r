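test_that("preprocess preserves constant scenes and sizes correctly", {
  img <- array(0, c(100, 100, 3))
  img[, , 1] <- 120; img[, , 2] <- 80; img[, , 3] <- 200
  out <- preprocess(img, seg_config(scale_factor = 0.4))
  expect_equal(dim(out), c(40, 40, 3))
  expect_true(all(out[, , 1] == 120 & out[, , 2] == 80 & out[, , 3] == 200))
  expect_error(preprocess(matrix(0, 5, 5)), "3 channel")
})

test_that("resize at scale 1 is the identity", {
  img <- array(random_channel(12, 15, seed = 2), c(12, 15, 1))[, , 1]
  expect_equal(resize_bicubic(img, 1), img)
})

test_that("Gaussian smoothing matches direct kernel arithmetic on an impulse", {
  m <- matrix(0, 11, 11); m[6, 6] <- 255
  out <- gaussian_smooth(m, sigma = 0.8, size = 5)
  half <- 2
  g1 <- exp(-((-half:half)^2) / (2 * 0.8^2))
  k <- outer(g1, g1); k <- k / sum(k)
  expect_equal(out[6, 6], k[3, 3] * 255)
  expect_equal(out[4:8, 4:8], k * 255)
  expect_equal(sum(out), 255)   # kernel sums to 1
})

test_that("HSV split follows the hexcone formulas on the 8-bit scale", {
  px <- function(r, g, b) {
    img <- array(0, c(1, 1, 3)); img[1, 1, ] <- c(r, g, b); split_hsv(img)
  }
  red <- px(255, 0, 0)
  expect_equal(red$S[1, 1], 255); expect_equal(red$V[1, 1], 255)
  gray <- px(128, 128, 128)
  expect_equal(gray$S[1, 1], 0); expect_equal(gray$V[1, 1], 128)
  mixed <- px(64, 128, 192)
  expect_equal(mixed$V[1, 1], 192)
  expect_equal(mixed$S[1, 1], round(255 * (192 - 64) / 192))  # 170
  black <- px(0, 0, 0)
  expect_equal(black$S[1, 1], 0)
})

test_that("value inversion is the 255-complement and an involution", {
  expect_equal(invert_value(matrix(0, 2, 2)), matrix(255, 2, 2))
  expect_equal(invert_value(matrix(255, 2, 2)), matrix(0, 2, 2))
  ch <- random_channel(20, 20, seed = 3)
  expect_equal(invert_value(invert_value(ch)), ch)
})

test_that("channel fusion saturates at 255 and maps white background to 0", {
  expect_equal(fuse_channels(matrix(10, 1, 1), matrix(20, 1, 1))[1, 1], 30)
  expect_equal(fuse_channels(matrix(200, 1, 1), matrix(100, 1, 1))[1, 1], 255)
  expect_equal(fuse_channels(matrix(200, 1, 1), matrix(100, 1, 1),
                             wide_range = TRUE)[1, 1], 300)
  # white mat pixel: S = 0, V = 255 -> V_inv = 0 -> fused 0
  expect_equal(fuse_channels(matrix(0, 1, 1), invert_value(matrix(255, 1, 1)))[1, 1], 0)
  expect_error(fuse_channels(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("background estimation and subtraction recover an isolated object", {
  bg_level <- 25
  scene <- matrix(bg_level, 140, 140)
  disk <- make_ellipse_mask(140, 140, 70, 70, 20, 20) == 255
  scene[disk] <- 180
  bg <- estimate_background(scene, 50)
  expect_equal(bg, matrix(bg_level, 140, 140))  # object removed
  expect_true(all(bg <= scene))                 # anti-extensive
  hc <- subtract_background(scene, bg)
  expect_equal(unique(hc[disk]), 180 - bg_level)
  expect_equal(unique(hc[!disk]), 0)
  expect_equal(subtract_background(scene, scene), matrix(0, 140, 140))
  expect_equal(subtract_background(scene, matrix(0, 140, 140)), scene)
  # subtraction floors at zero
  expect_equal(subtract_background(matrix(5, 2, 2), matrix(9, 2, 2)),
               matrix(0, 2, 2))
})

test_that("Otsu threshold equals the exhaustive search and ties go low", {
  two <- matrix(c(rep(50, 32), rep(200, 32)), 8, 8)
  expect_identical(otsu_threshold(two), 50L)
  expect_identical(oracle_otsu(two), 50L)

  # bimodal blobs, several seeds
  for (seed in 1:5) {
    set.seed(seed)
    v <- c(pmin(pmax(round(rnorm(300, 60, 12)), 0), 255),
           pmin(pmax(round(rnorm(150, 190, 15)), 0), 255))
    I <- matrix(v, 30, 15)
    expect_identical(otsu_threshold(I), oracle_otsu(I),
                     info = paste("bimodal seed", seed))
  }
  expect_error(otsu_threshold(matrix(7, 4, 4)), "degenerate")
})

test_that("binarization uses a strict inequality", {
  expect_equal(binarize(matrix(0, 2, 2), 0), matrix(0, 2, 2))
  expect_equal(binarize(matrix(255, 2, 2), 0), matrix(255, 2, 2))
  two <- matrix(c(50, 200, 50, 200), 2, 2)
  expect_equal(binarize(two, 50), matrix(c(0, 255, 0, 255), 2, 2))
})

test_that("hole filling fills enclosed holes, keeps border-open concavities", {
  ring <- make_ellipse_mask(30, 30, 15, 15, 10, 10)
  hole <- make_ellipse_mask(30, 30, 15, 15, 4, 4) == 255
  ring[hole] <- 0
  filled <- fill_holes(ring)
  expect_true(all(filled[hole] == 255))
  expect_true(all(filled >= ring))            # extensive
  expect_equal(fill_holes(filled), filled)    # idempotent

  cshape <- matrix(0, 20, 20)
  cshape[5:15, 5:15] <- 255
  cshape[8:12, 10:20] <- 0                    # concavity open to right border
  expect_equal(fill_holes(cshape), cshape)

  # agrees with reconstruction-by-erosion from a border-valued marker
  for (seed in 1:4) {
    m <- clean_mask(random_mask(25, 25, p = 0.45, seed = seed), 1)
    expect_equal(fill_holes(m), oracle_fill_holes(m),
                 info = paste("reconstruction seed", seed))
  }
})

test_that("a hole reachable only diagonally still fills (4-connected background)", {
  m <- matrix(0, 5, 5)
  m[2:4, 2:4] <- 255
  m[3, 3] <- 0   # interior hole
  m[2, 2] <- 0   # diagonal opening in the ring
  filled <- fill_holes(m)
  expect_equal(filled[3, 3], 255)   # diagonal path does not drain the hole
  expect_equal(filled[2, 2], 0)     # 4-connected to the border, stays open
})

test_that("segment finds every fruit and none on an empty mat", {
  sc <- generate_scene(scene_params(seed = 7))
  mask <- segment(sc$image)
  expect_equal(label_components(mask)$n, nrow(sc$fruits))
  expect_equal(dim(mask), dim(resize_mask_nearest(sc$mask, 0.4)))

  empty <- generate_scene(scene_params(n_fruits = 0L, seed = 3))
  expect_warning(em <- segment(empty$image), "fruit-free")
  expect_lt(mean(em != 0), 0.005)

  flat <- generate_scene(scene_params(n_fruits = 0L, noise_sigma = 0,
                                      fold_amplitude = 0, shadow_strength = 0,
                                      seed = 3))
  expect_warning(fm <- segment(flat$image), "degenerate")
  expect_true(all(fm == 0))
  # with the contrast guard disabled, the flat mat hits the Otsu error path
  expect_warning(segment(flat$image, seg_config(min_contrast = 0)),
                 "degenerate histogram")
})

test_that("segmentation is equivariant under horizontal mirroring", {
  sc <- generate_scene(scene_params(seed = 11))
  mask <- segment(sc$image)
  flipped <- sc$image[, dim(sc$image)[2]:1, , drop = FALSE]
  mask_f <- segment(flipped)
  expect_equal(mask_f[, ncol(mask_f):1], mask, ignore_attr = TRUE)
})
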