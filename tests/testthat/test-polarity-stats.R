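test_that("circle, ellipse and square shapes fit to expected calipers", {
  circ <- disc_mask(30, 30, 10)
  s <- fit_nucleus(circ)
  expect_equal(s$ellipticity, 1, tolerance = 0.05)

  nuc <- nucleus_shape(c(32, 32), 40, 20, 30)
  img <- render_polarity_image(list(nuc), 0, 12, c(64, 64), 1, seed = 1)
  s2 <- fit_nucleus(get_channel(img, "nucleus"))
  expect_equal(s2$ellipticity, 2, tolerance = 0.1)
  expect_lt(axial_distance(s2$orientation_deg, 30), 3)
  expect_equal(s2$height_um, 40, tolerance = 2)
  expect_equal(s2$centroid_um, c(32, 32), tolerance = 0.5)

  sq <- make_mask(function(x, y) x >= 20 & x <= 40 & y >= 20 & y <= 40)
  s3 <- fit_nucleus(sq)
  # rotating-calipers expectation: diagonal over side
  expect_equal(s3$ellipticity, sqrt(2), tolerance = sqrt(2) * 0.1)
  # independent brute-force caliper oracle on the same pixel cloud
  px <- sq$pixels
  xs <- (col(px)[px == 1] - 1); ys <- -(row(px)[px == 1] - 1)
  ext <- vapply(seq(0, 179.5, 0.5), function(th) {
    p <- xs * cos(th * pi / 180) + ys * sin(th * pi / 180)
    max(p) - min(p) + 1
  }, numeric(1))
  expect_equal(s3$height_um, max(ext), tolerance = 1e-6)
  expect_equal(s3$width_um, min(ext), tolerance = 1e-6)

  expect_error(fit_nucleus(label_image(matrix(0, 16, 16), 1)), "empty")
  line <- make_mask(function(x, y) y == 10 & x >= 5 & x <= 40)
  expect_error(fit_nucleus(line), "degenerate|small")
})

test_that("ellipticity is at least 1 and stable under 90-degree rotation", {
  withr::with_seed(70, {
    for (rep in 1:10) {
      e_true <- stats::runif(1, 1, 3)
      h <- 30; w <- h / e_true
      th <- stats::runif(1, 0, 180)
      nuc <- nucleus_shape(c(40, 40), h, w, th)
      img <- render_polarity_image(list(nuc), 0, 20, c(80, 80), 1, seed = rep)
      m <- get_channel(img, "nucleus")
      s <- fit_nucleus(m)
      expect_gte(s$ellipticity, 1)
      rot <- label_image(t(m$pixels)[ncol(m$pixels):1, ], 1)  # 90-deg rotation
      s_rot <- fit_nucleus(rot)
      expect_equal(s_rot$ellipticity, s$ellipticity, tolerance = 0.05)
    }
  })
})

test_that("orientation and ellipticity recover over 200 random nuclei", {
  withr::with_seed(71, {
    err_th <- numeric(0); err_e <- numeric(0)
    for (rep in 1:200) {
      e_true <- stats::runif(1, 1.3, 3)  # clearly anisotropic
      h <- stats::runif(1, 24, 36); w <- h / e_true
      th <- stats::runif(1, 0, 180)
      nuc <- nucleus_shape(c(40, 40), h, w, th)
      img <- render_polarity_image(list(nuc), 0, 20, c(80, 80), 1, seed = rep)
      s <- fit_nucleus(get_channel(img, "nucleus"))
      err_th <- c(err_th, axial_distance(s$orientation_deg, th))
      err_e <- c(err_e, abs(s$ellipticity - e_true) / e_true)
    }
    expect_lt(stats::median(err_th), 3)
    expect_lt(stats::median(err_e), 0.10)
  })
})

test_that("first-quadrant projection maps alignment with migration to 90", {
  expect_equal(nuclear_angle_first_quadrant(90, 90), 90)   # parallel
  expect_equal(nuclear_angle_first_quadrant(0, 90), 0)     # along scratch
  expect_equal(nuclear_angle_first_quadrant(150, 90), 30)
  expect_equal(nuclear_angle_first_quadrant(45, 0), 45)
  # axial symmetry: theta and theta + 180 identical
  for (th in c(10, 75, 120)) {
    expect_equal(nuclear_angle_first_quadrant(th, 30),
                 nuclear_angle_first_quadrant(th + 180, 30))
    # mirror symmetry about the reference
    expect_equal(nuclear_angle_first_quadrant(30 + th, 30),
                 nuclear_angle_first_quadrant(30 - th, 30))
  }
  expect_true(all(nuclear_angle_first_quadrant(seq(0, 355, 5), 77) >= 0 &
                    nuclear_angle_first_quadrant(seq(0, 355, 5), 77) <= 90))
})

test_that("organelle polarization angle follows the stated conventions", {
  nuc <- nucleus_shape(c(50, 50), 10, 10, 0)
  # along the reference (+x): angle 0
  expect_equal(organelle_polarization_angle(nuc, c(58, 50), 0), 0)
  # opposite: 180
  expect_equal(organelle_polarization_angle(nuc, c(42, 50), 0), 180)
  # image-space y is down: an organelle above the nucleus is at +90
  expect_equal(organelle_polarization_angle(nuc, c(50, 42), 0), 90)
  expect_error(organelle_polarization_angle(nuc, c(50, 50), 0), "coincide")
})

test_that("rendered organelles are recovered at their programmed angles", {
  true_angles <- c(0, 37, 90, 180, 270)
  nuclei <- lapply(seq_along(true_angles), function(i) {
    nucleus_shape(c(25 + 40 * (i - 1), 30), 16, 8, 0)
  })
  img <- render_polarity_image(nuclei, true_angles, 12,
                               image_shape_px = c(120, 400),
                               pixel_size_um = 0.5, seed = 2)
  m <- measure_polarity_image(img)
  m <- m[order(m$x_um), ]
  expect_equal(nrow(m), 5)
  expect_true(all(angle_distance(m$organelle_angle_deg, true_angles) <= 5))
})

test_that("empty nucleus lists yield pure noise and zero detections", {
  img <- render_polarity_image(list(), numeric(0), 10, c(48, 48), 1,
                               seed = 3, noise_sd = 0.1)
  expect_equal(sum(img$pixels[, , 1]), 0)
  m <- measure_polarity_image(img)
  expect_equal(nrow(m), 0)
})

test_that("polarized fraction supports uni- and bidirectional windows", {
  expect_equal(polarized_fraction(rep(10, 7), 10), 1)
  expect_equal(polarized_fraction(rep(180, 4), 0, front_rear = TRUE), 1)
  expect_equal(polarized_fraction(c(0, 180, 90, 270), 0, 120,
                                  front_rear = TRUE), 0.5)
  u <- withr::with_seed(72, stats::runif(1000, 0, 360))
  se <- sqrt((1 / 3) * (2 / 3) / 1000)
  expect_lt(abs(polarized_fraction(u, 45) - 1 / 3), 3 * se)
})
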