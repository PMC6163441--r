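test_that("8-connected labeling matches the flood-fill oracle", {
  diag2 <- matrix(0, 4, 4); diag2[1, 1] <- 255; diag2[2, 2] <- 255
  expect_equal(label_components(diag2)$n, 1)   # diagonal touch joins

  two <- matrix(0, 6, 10); two[2:4, 2:3] <- 255; two[2:4, 7:9] <- 255
  expect_equal(label_components(two)$n, 2)

  expect_equal(label_components(matrix(0, 5, 5))$n, 0)

  for (seed in 1:5) {
    m <- random_mask(25, 30, p = 0.25, seed = seed)
    got <- label_components(m)
    ora <- oracle_label(m)
    expect_equal(got$n, ora$n, info = paste("count seed", seed))
    expect_equal(as.vector(got$labels), as.vector(ora$labels),
                 info = paste("labels seed", seed))
  }
})

test_that("ellipse axes follow the unit-pixel moment convention", {
  single <- ellipse_axes(0, 0)
  expect_equal(unname(single["major_axis_px"]), 4 * sqrt(1 / 12))
  expect_equal(unname(single["minor_axis_px"]), 4 * sqrt(1 / 12))

  # filled axis-aligned ellipse, semi-axes 40 and 20 px
  m <- make_ellipse_mask(120, 160, 60, 80, 40, 20)
  px <- which(m == 255, arr.ind = TRUE) - 1
  ax <- ellipse_axes(px[, 1], px[, 2])
  expect_lt(abs(ax["major_axis_px"] - 80) / 80, 0.02)
  expect_lt(abs(ax["minor_axis_px"] - 40) / 40, 0.02)
  expect_lt(abs(ax["orientation"]), 0.02)

  # same ellipse rotated 30 degrees
  m30 <- make_ellipse_mask(160, 160, 80, 80, 40, 20, theta = pi / 6)
  px30 <- which(m30 == 255, arr.ind = TRUE) - 1
  ax30 <- ellipse_axes(px30[, 1], px30[, 2])
  expect_lt(abs(ax30["major_axis_px"] - ax["major_axis_px"]) /
              ax["major_axis_px"], 0.02)
  expect_lt(abs(ax30["minor_axis_px"] - ax["minor_axis_px"]) /
              ax["minor_axis_px"], 0.02)
  expect_lt(abs(ax30["orientation"] - pi / 6), 0.03)

  # translation invariance
  axt <- ellipse_axes(px[, 1] + 13, px[, 2] + 7)
  expect_equal(unname(axt), unname(ax))
})

test_that("digital disks measure close to their diameter and major >= minor", {
  for (r in c(10, 25, 60)) {
    m <- make_ellipse_mask(2 * r + 21, 2 * r + 21, r + 10, r + 10, r, r)
    px <- which(m == 255, arr.ind = TRUE) - 1
    ax <- ellipse_axes(px[, 1], px[, 2])
    expect_lt(abs(ax["major_axis_px"] - 2 * r) / (2 * r), 0.03)
    expect_lt(abs(ax["minor_axis_px"] - 2 * r) / (2 * r), 0.03)
    expect_gte(ax["major_axis_px"], ax["minor_axis_px"])
  }
})

test_that("measure_components reports area, centroid and conserves pixels", {
  expect_equal(nrow(measure_components(matrix(0, 5, 5))), 0)

  sq <- matrix(0, 12, 12); sq[4:8, 6:10] <- 255
  tab <- measure_components(sq, "sq")
  expect_equal(tab$area_px, 25)
  expect_equal(tab$centroid_row, 5)   # 0-based center of rows 4:8 -> 3..7
  expect_equal(tab$centroid_col, 7)

  m <- random_mask(40, 40, p = 0.3, seed = 8)
  tab2 <- measure_components(m)
  expect_equal(sum(tab2$area_px), sum(m != 0))
  expect_equal(tab2$label, seq_len(nrow(tab2)))
  expect_true(all(tab2$major_axis_px >= tab2$minor_axis_px))
})

test_that("component areas track the generator's painted areas", {
  sc <- generate_scene(scene_params(seed = 3))
  tab <- measure_components(sc$mask)
  expect_equal(nrow(tab), nrow(sc$fruits))
  # order components to fruits by centroid proximity
  m <- match_to_reference(
    tab,
    data.frame(fruit_id = sc$fruits$fruit_id,
               pos_row = sc$fruits$center_row,
               pos_col = sc$fruits$center_col))
  expect_equal(nrow(m$pairs), nrow(sc$fruits))
  idx <- match(m$pairs$fruit_id, sc$fruits$fruit_id)
  expect_true(all(abs(m$pairs$area_px - sc$fruits$painted_area_px[idx]) /
                    sc$fruits$painted_area_px[idx] < 0.05))
})

test_that("reference matching is stable under jitter and reports leftovers", {
  comp <- data.frame(image_id = "i", label = 1:3,
                     area_px = c(100, 100, 100),
                     centroid_row = c(10, 50, 90),
                     centroid_col = c(10, 50, 90),
                     major_axis_px = c(12, 12, 12),
                     minor_axis_px = c(10, 10, 10),
                     orientation_rad = 0)
  ref <- data.frame(fruit_id = c("a", "b", "c"),
                    pos_row = c(10, 50, 90), pos_col = c(10, 50, 90))
  m <- match_to_reference(comp, ref)
  expect_equal(m$pairs$fruit_id, c("a", "b", "c"))
  expect_equal(m$pairs$match_dist_px, c(0, 0, 0))

  jit <- ref; jit$pos_row <- jit$pos_row + c(3, -4, 2)
  mj <- match_to_reference(comp, jit, gate = 15)
  expect_equal(mj$pairs$fruit_id[order(mj$pairs$label)],
               m$pairs$fruit_id[order(m$pairs$label)])

  far <- rbind(ref, data.frame(fruit_id = "ghost", pos_row = 200, pos_col = 200))
  mf <- match_to_reference(comp, far, gate = 15)
  expect_equal(mf$unmatched_reference, "ghost")
  expect_length(mf$unmatched_components, 0)

  # two references equidistant from one component: ambiguous
  amb <- data.frame(fruit_id = c("L", "R"), pos_row = c(10, 10),
                    pos_col = c(8, 12))
  expect_error(match_to_reference(comp[1, ], amb, gate = 15), "ambiguous")
})
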