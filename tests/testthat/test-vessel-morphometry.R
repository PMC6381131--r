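test_that("vascular density is the foreground fraction of the ROI", {
  half <- make_mask(function(x, y) x < 32, nr = 64, nc = 64)
  expect_equal(vascular_density(half), 50)
  expect_equal(vascular_density(label_image(matrix(0, 16, 16), 1)), 0)
  # linear in foreground area and translation invariant
  d1 <- vascular_density(disc_mask(20, 20, 8, 100, 100))
  d2 <- vascular_density(disc_mask(60, 70, 8, 100, 100))
  expect_equal(d1, d2)
  # roi restriction
  m <- make_mask(function(x, y) x < 10 & y < 10, nr = 40, nc = 40)
  expect_equal(vascular_density(m, roi_rect(0, 0, 10, 10)), 100)
  expect_error(vascular_density(m, roi_rect(30, 30, 60, 60)), "outside")
})

test_that("branch points match hand-enumerated toy figures", {
  plus <- make_mask(function(x, y) {
    (y >= 18 & y <= 22) | (x >= 18 & x <= 22)
  }, nr = 41, nc = 41)
  expect_equal(branch_points(plus, merge_radius_um = 10)$count, 1)

  aitch <- make_mask(function(x, y) {
    (x >= 4 & x <= 8) | (x >= 32 & x <= 36) | (y >= 18 & y <= 22 & x >= 4 & x <= 36)
  }, nr = 41, nc = 41)
  expect_equal(branch_points(aitch, merge_radius_um = 10)$count, 2)

  # straight bar: no junctions; empty mask: zero
  bar <- make_mask(function(x, y) y >= 18 & y <= 22, nr = 41, nc = 41)
  expect_equal(branch_points(bar, merge_radius_um = 10)$count, 0)
  expect_equal(branch_points(label_image(matrix(0, 20, 20), 1))$count, 0)
})

test_that("branch points are invariant under 90-degree rotation", {
  net <- render_vessel_network(6, 0.04, image_shape_px = c(256, 256),
                               pixel_size_um = 2, seed = 4)
  mr <- 2 * net$ground_truth$stroke_width_um
  n0 <- branch_points(net$image, merge_radius_um = mr)$count
  px <- net$image$pixels
  rot <- label_image(t(px)[ncol(px):1, ], net$image$pixel_size_um)
  expect_equal(branch_points(rot, merge_radius_um = mr)$count, n0)
})

test_that("synthetic networks report exact density and junction counts", {
  for (s in 1:5) {
    net <- render_vessel_network(12, 0.04, seed = s)
    expect_equal(vascular_density(net$image),
                 100 * net$ground_truth$true_density, tolerance = 1e-12)
    bp <- branch_points(net$image,
                        merge_radius_um = 2 * net$ground_truth$stroke_width_um)
    expect_equal(bp$count, 12)
  }
  # single junction: a "+"-like cross
  one <- render_vessel_network(1, 0.03, image_shape_px = c(128, 128),
                               pixel_size_um = 2, seed = 9)
  expect_equal(branch_points(one$image,
                             merge_radius_um = 2 * one$ground_truth$stroke_width_um)$count,
               1)
})

test_that("radial outgrowth averages per-sector vascular fronts", {
  # full disc of radius 40 um about the centre
  disc <- disc_mask(50, 50, 40, nr = 101, nc = 101)
  r <- radial_outgrowth(disc, c(50, 50))
  expect_equal(as.numeric(r), 40, tolerance = 1.5)

  # four leaflets at programmed radii 10/20/30/40 um -> mean 25
  leaf <- make_mask(function(x, y) {
    dx <- x - 50; dy <- -(y - 50)
    d <- sqrt(dx^2 + dy^2)
    a <- (atan2(dy, dx) * 180 / pi) %% 360
    (a < 90 & d <= 10) | (a >= 90 & a < 180 & d <= 20) |
      (a >= 180 & a < 270 & d <= 30) | (a >= 270 & d <= 40)
  }, nr = 101, nc = 101)
  r4 <- radial_outgrowth(leaf, c(50, 50), n_sectors = 4)
  expect_equal(as.numeric(r4), mean(c(10, 20, 30, 40)), tolerance = 1.5)

  # empty half-plane: uncovered sectors excluded with a warning
  half <- make_mask(function(x, y) x >= 50 & (x - 50)^2 + (y - 50)^2 <= 900,
                    nr = 101, nc = 101)
  expect_warning(rh <- radial_outgrowth(half, c(50, 50), n_sectors = 4),
                 "empty sector")
  expect_equal(as.numeric(rh), 30, tolerance = 2)
  expect_error(radial_outgrowth(label_image(matrix(0, 10, 10), 1), c(5, 5)),
               "empty mask")
})

test_that("front counts normalize to 100 um and per sprout", {
  ann <- data.frame(
    x = runif(40), y = runif(40),
    label = c(rep("sprout", 10), rep("filopodium", 30))
  )
  fc <- front_counts(ann, 500)
  expect_equal(fc$sprouts_per_100um, 2)
  expect_equal(fc$filopodia_per_100um, 6)
  expect_equal(fc$filopodia_per_sprout, 3)
  # brute-force tally oracle
  expect_equal(fc$n_sprouts, sum(ann$label == "sprout"))
  expect_equal(fc$n_filopodia, sum(ann$label == "filopodium"))

  none <- front_counts(data.frame(label = rep("sprout", 4)), 200)
  expect_equal(none$filopodia_per_sprout, 0)
  orphan <- front_counts(data.frame(label = rep("filopodium", 3)), 200)
  expect_true(is.na(orphan$filopodia_per_sprout))
  expect_identical(orphan$flag, "no_sprouts")
})

test_that("leakage and tuft area fractions follow their definitions", {
  a <- make_mask(function(x, y) x < 20 & y < 32, nr = 64, nc = 64)  # 10% of roi
  b <- make_mask(function(x, y) x >= 40, nr = 64, nc = 64)
  expect_equal(area_fraction_metrics(a, b, mode = "leakage"),
               100 * sum(a$pixels) / (64 * 64))
  # a inside b: zero leakage
  sub <- make_mask(function(x, y) x >= 45 & x < 50, nr = 64, nc = 64)
  expect_equal(area_fraction_metrics(sub, b, mode = "leakage"), 0)
  # tuft mode: area ratio
  quarter <- make_mask(function(x, y) x >= 40 & y < 16, nr = 64, nc = 64)
  expect_equal(area_fraction_metrics(quarter, b, mode = "tuft"), 25)
  empty <- label_image(matrix(0, 64, 64), 1)
  expect_error(area_fraction_metrics(a, empty, mode = "tuft"), "zero area")
})

test_that("normalized intensity recovers programmed fold changes", {
  img <- make_mask(function(x, y) x < 0, nr = 64, nc = 64)  # zeros
  px <- img$pixels
  px[] <- 20                      # background level
  px[, 1:16] <- 100               # vessel signal
  img <- label_image(px, 1)
  vr <- list(roi_rect(0, 0, 16, 64))
  br <- list(roi_rect(32, 0, 16, 64))
  expect_equal(as.numeric(normalized_intensity(img, vr, br, 80)), 1)
  expect_equal(as.numeric(normalized_intensity(img, br, br, 80)), 0)
  flagged <- normalized_intensity(img, br, vr, 80)  # background > signal
  expect_identical(attr(flagged, "flag"), "background_exceeds_signal")

  # programmed 12x contrast over a control mean, with mild noise
  withr::with_seed(77, {
    ctrl <- 50
    base <- matrix(stats::rnorm(128 * 128, 10, 1), 128, 128)
    base[, 1:32] <- base[, 1:32] + 12 * ctrl
    noisy <- label_image(base, 1)
    v10 <- lapply(seq(0, 117, length.out = 10), function(y0)
      roi_rect(0, y0, 32, 10))
    bg <- list(roi_rect(64, 0, 64, 128))
    fold <- normalized_intensity(noisy, v10, bg, ctrl)
    expect_equal(as.numeric(fold), 12, tolerance = 0.5 / 12)
  })
})

test_that("skeletonize reduces strokes to thin connected centrelines", {
  bar <- make_mask(function(x, y) y >= 18 & y <= 24, nr = 41, nc = 41)
  sk <- skeletonize(bar)
  # interior columns thin to a single centreline pixel (stroke ends may
  # erode by up to the stroke half-width)
  expect_true(all(colSums(sk)[5:37] == 1))
  # skeleton is a subset of the stroke
  expect_true(all(bar$pixels[sk == 1] == 1))
})
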