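cal1 <- calibration(512, 512)  # 1 um/px

test_that("detect_centroids finds disc centroids to sub-pixel accuracy", {
  one <- disc_mask(50, 60, 8, nr = 128, nc = 128)
  det <- detect_centroids(one)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 50), 0.5)
  expect_lt(abs(det$y_px - 60), 0.5)

  two <- make_mask(function(x, y) {
    (x - 30)^2 + (y - 30)^2 <= 64 | (x - 90)^2 + (y - 90)^2 <= 64
  }, nr = 128, nc = 128)
  expect_equal(nrow(detect_centroids(two)), 2)

  empty <- label_image(matrix(0, 32, 32), 1)
  expect_equal(nrow(detect_centroids(empty)), 0)

  # min_area filters specks
  speck <- label_image(matrix(c(rep(0, 100), 1, rep(0, 923)), 32, 32), 1)
  expect_equal(nrow(detect_centroids(speck, min_area_px = 5)), 0)
})

test_that("unambiguous constant-velocity cells link without switches", {
  t1 <- trajectory(1, seq(0, 90, 10), seq(50, 140, 10), rep(100, 10))
  t2 <- trajectory(2, seq(0, 90, 10), seq(50, 140, 10), rep(300, 10))
  det <- rasterize_and_detect(list(t1, t2), cal1, c(512, 512))
  out <- link_tracks(det, max_step_um = 20, cal1)
  expect_equal(length(out), 2)
  expect_true(all(vapply(out, nrow, integer(1)) == 10))
  # positions exactly the ground truth (disc centroids at pixel centres)
  ys <- sort(vapply(out, function(tr) tr$y_um[1], numeric(1)))
  expect_equal(ys, c(100, 300))
  for (tr in out) expect_equal(tr$x_um, t1$x_um)
})

test_that("a vanishing detection terminates its track; reappearance starts a new one", {
  det <- data.frame(
    frame = c(0, 1, 2, 4, 5),
    x_px = c(10, 12, 14, 18, 20) + 100,
    y_px = rep(50, 5)
  )
  # frame 3 missing entirely -> frames must be consecutive: add an
  # unrelated detection to keep the frame grid complete
  det <- rbind(det, data.frame(frame = 3, x_px = 400, y_px = 400))
  out <- link_tracks(det, max_step_um = 5, cal1)
  lens <- sort(vapply(out, nrow, integer(1)))
  expect_equal(lens, c(1, 2, 3))  # 3-frame track, gap, then 2-frame track
})

test_that("linking is invariant to detection order within frames", {
  withr::with_seed(60, {
    det <- do.call(rbind, lapply(0:5, function(f) {
      data.frame(frame = f,
                 x_px = c(50, 150, 250) + f * 4 + stats::rnorm(3, 0, 0.5),
                 y_px = c(60, 160, 260) + stats::rnorm(3, 0, 0.5))
    }))
    out1 <- link_tracks(det, 15, cal1)
    shuf <- det[sample(nrow(det)), ]
    out2 <- link_tracks(shuf, 15, cal1)
    key <- function(tracks) {
      sort(vapply(tracks, function(tr) paste(round(tr$x_um, 6), collapse = ","),
                  character(1)))
    }
    expect_identical(key(out1), key(out2))
  })
})

test_that("every detection lands in exactly one track", {
  withr::with_seed(61, {
    det <- do.call(rbind, lapply(0:7, function(f) {
      data.frame(frame = f, x_px = stats::runif(6, 0, 500),
                 y_px = stats::runif(6, 0, 500))
    }))
    out <- link_tracks(det, 80, cal1)
    n_pos <- sum(vapply(out, nrow, integer(1)))
    expect_equal(n_pos, nrow(det))
    all_pts <- do.call(rbind, lapply(out, function(tr)
      cbind(tr$t_min / 10, round(tr$x_um, 6), round(tr$y_um, 6))))
    expect_equal(nrow(unique(as.data.frame(all_pts))), nrow(det))
  })
})

test_that("greedy linking agrees with the minimal-assignment oracle when unambiguous", {
  withr::with_seed(62, {
    n_checked <- 0
    for (rep in 1:80) {
      n <- sample(2:6, 1)
      prev <- cbind(stats::runif(n, 0, 400), stats::runif(n, 0, 400))
      cur <- prev + matrix(stats::rnorm(2 * n, 0, 4), n, 2)
      max_step <- 15
      # unambiguity guard: all pairwise distance gaps > max_step / 10
      d <- as.vector(outer(seq_len(n), seq_len(n), function(i, j) {
        sqrt((prev[i, 1] - cur[j, 1])^2 + (prev[i, 2] - cur[j, 2])^2)
      }))
      d <- sort(d[d <= max_step])
      if (length(d) > 1 && min(diff(d)) <= max_step / 10) next
      n_checked <- n_checked + 1
      det <- rbind(data.frame(frame = 0, x_px = prev[, 1], y_px = prev[, 2]),
                   data.frame(frame = 1, x_px = cur[, 1], y_px = cur[, 2]))
      out <- link_tracks(det, max_step, cal1)
      # greedy links as pairs (prev index -> cur index)
      two_frame <- Filter(function(tr) nrow(tr) == 2, out)
      got <- lapply(two_frame, function(tr) round(c(tr$x_um, tr$y_um), 6))
      oracle <- oracle_min_assignment(prev, cur, max_step)
      want <- list()
      for (i in seq_len(n)) {
        if (!is.na(oracle[i]))
          want[[length(want) + 1]] <- round(c(prev[i, 1], cur[oracle[i], 1],
                                              prev[i, 2], cur[oracle[i], 2]), 6)
      }
      expect_equal(length(got), length(want))
      expect_setequal(vapply(got, paste, character(1), collapse = ","),
                      vapply(want, paste, character(1), collapse = ","))
    }
    expect_gt(n_checked, 10)
  })
})

test_that("simulated well-separated cells are recovered exactly", {
  wound0 <- wound_geometry(0)
  cfg <- simulation_config(seed = 63, n_cells = 9, n_frames = 12,
                           bias_kappa = 2, persistence_weight = 0.2)
  sim <- simulate_tracks(cfg, wound0)
  # re-anchor tracks on a coarse grid so min spacing >> max per-frame step
  truth <- lapply(seq_along(sim$tracks), function(i) {
    tr <- sim$tracks[[i]]
    trajectory(i, tr$t_min,
               tr$x_um - tr$x_um[1] + 80 + 160 * ((i - 1) %% 3),
               tr$y_um - tr$y_um[1] + 80 + 160 * ((i - 1) %/% 3))
  })
  det <- rasterize_and_detect(truth, cal1, c(512, 512))
  out <- link_tracks(det, max_step_um = 25, cal1)
  expect_equal(length(out), 9)
  # optimal label matching = nearest starting point
  starts_truth <- t(vapply(truth, function(tr) c(tr$x_um[1], tr$y_um[1]),
                           numeric(2)))
  for (tr in out) {
    expect_equal(nrow(tr), 12)
    i <- which.min((starts_truth[, 1] - tr$x_um[1])^2 +
                     (starts_truth[, 2] - tr$y_um[1])^2)
    expect_lt(max(abs(tr$x_um - truth[[i]]$x_um)), 0.75)
    expect_lt(max(abs(tr$y_um - truth[[i]]$y_um)), 0.75)
  }
})

test_that("out-of-order or gapped frame grids are rejected", {
  det <- data.frame(frame = c(0, 2), x_px = c(1, 2), y_px = c(1, 2))
  expect_error(link_tracks(det, 5, cal1), "consecutive")
  expect_error(link_tracks(data.frame(frame = 0, x_px = 1, y_px = 1), 0, cal1),
               "max_step")
})
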