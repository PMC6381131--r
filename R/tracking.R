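#' Detect cell centroids by connected components
#'
#' Thresholds a single-channel image and labels connected components
#' (8-connectivity); each component above the area cutoff becomes one
#' detection with an unweighted pixel-centre centroid (0-based pixel
#' coordinates).
#'
#' @param image single-channel [label_image()].
#' @param min_area_px minimum component area in pixels (default 5).
#' @param threshold intensity threshold; pixels strictly above it are
#'   foreground (default 0.5).
#' @return data.frame with columns `x_px`, `y_px`, `area_px` (possibly
#'   0 rows).
#' @export
detect_centroids <- function(image, min_area_px = 5, threshold = 0.5) {
  stopifnot(inherits(image, "label_image"))
  px <- image$pixels
  if (!is.matrix(px)) stop("'image' must be single-channel", call. = FALSE)
  fg <- matrix(as.numeric(px > threshold), nrow(px), ncol(px))
  if (!any(fg == 1))
    return(data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0)))
  lab <- label_components8(fg)
  ids <- seq_len(max(lab))
  rows <- row(lab)[lab > 0]; cols <- col(lab)[lab > 0]; labs <- lab[lab > 0]
  area <- tabulate(labs, nbins = length(ids))
  out <- data.frame(
    x_px = tapply(cols - 1, labs, mean),
    y_px = tapply(rows - 1, labs, mean),
    area_px = area
  )
  out <- out[out$area_px >= min_area_px, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link per-frame detections into trajectories
#'
#' Greedy global nearest-neighbour linking: between consecutive frames all
#' candidate detection pairs are sorted by ascending distance (in um) and
#' accepted while the distance is within `max_step_um` and both endpoints
#' are unassigned. Unmatched detections start new tracks; a track that
#' misses a frame terminates (no gap closing). Ties in distance break on
#' the lower (previous-index, current-index) pair, so linking is
#' deterministic and invariant to detection order within a frame.
#'
#' @param detections data.frame with columns `frame` (0-based,
#'   consecutive), `x_px`, `y_px`.
#' @param max_step_um maximum per-frame displacement, um.
#' @param calibration a [calibration()] converting pixels to um.
#' @param frame_interval_min minutes between frames (default 10), used for
#'   trajectory time stamps.
#' @return list of [trajectory()] objects (positions in um).
#' @export
link_tracks <- function(detections, max_step_um, calibration,
                        frame_interval_min = 10) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x_px", "y_px") %in% names(detections)),
            inherits(calibration, "calibration"))
  if (max_step_um <= 0) stop("'max_step_um' must be > 0", call. = FALSE)
  if (nrow(detections) == 0) return(list())
  frames <- sort(unique(detections$frame))
  if (any(diff(frames) != 1))
    stop("frames must be consecutive", call. = FALSE)
  ps <- calibration$pixel_size_um

  # canonical within-frame order for deterministic tie-breaking
  by_frame <- lapply(frames, function(f) {
    d <- detections[detections$frame == f, c("x_px", "y_px"), drop = FALSE]
    d <- d[order(d$x_px, d$y_px), , drop = FALSE] * ps
    as.matrix(d)
  })

  # active tracks: list of (rows of (frame, x_um, y_um)); open = index of
  # the track currently ending at each detection of the previous frame
  tracks <- lapply(seq_len(nrow(by_frame[[1]])), function(i) {
    cbind(frames[1], by_frame[[1]][i, 1], by_frame[[1]][i, 2])
  })
  open <- seq_along(tracks)

  for (k in seq_along(frames)[-1]) {
    prev <- by_frame[[k - 1]]; cur <- by_frame[[k]]
    n_prev <- nrow(prev); n_cur <- nrow(cur)
    link_of <- rep(NA_integer_, n_cur)
    if (n_prev > 0 && n_cur > 0) {
      dx <- outer(prev[, 1], cur[, 1], "-")
      dy <- outer(prev[, 2], cur[, 2], "-")
      dist <- sqrt(dx^2 + dy^2)
      cand <- which(dist <= max_step_um, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(dist[cand], cand[, 1], cand[, 2])
        used_prev <- logical(n_prev); used_cur <- logical(n_cur)
        for (ci in ord) {
          i <- cand[ci, 1]; j <- cand[ci, 2]
          if (!used_prev[i] && !used_cur[j]) {
            used_prev[i] <- TRUE; used_cur[j] <- TRUE
            link_of[j] <- i
          }
        }
      }
    }
    new_open <- integer(n_cur)
    for (j in seq_len(n_cur)) {
      row <- cbind(frames[k], cur[j, 1], cur[j, 2])
      if (!is.na(link_of[j])) {
        ti <- open[link_of[j]]
        tracks[[ti]] <- rbind(tracks[[ti]], row)
        new_open[j] <- ti
      } else {
        tracks[[length(tracks) + 1]] <- row
        new_open[j] <- length(tracks)
      }
    }
    open <- new_open
  }

  lapply(seq_along(tracks), function(i) {
    m <- tracks[[i]]
    trajectory(i, m[, 1] * frame_interval_min, m[, 2], m[, 3])
  })
}

#' Render point positions as discs and detect them frame by frame
#'
#' Convenience for closing the simulate-render-detect-link loop: stamps a
#' disc at each trajectory position per frame and runs [detect_centroids()].
#'
#' @param tracks list of [trajectory()] (positions um, image space).
#' @param calibration a [calibration()].
#' @param image_shape_px (rows, cols).
#' @param radius_um disc radius (default 6 um, a cell-body scale blob).
#' @return detections data.frame with `frame`, `x_px`, `y_px`, `area_px`.
#' @export
rasterize_and_detect <- function(tracks, calibration,
                                 image_shape_px = c(512, 512),
                                 radius_um = 6) {
  ps <- calibration$pixel_size_um
  n_frames <- nrow(tracks[[1]])
  nr <- image_shape_px[1]; nc <- image_shape_px[2]
  ctr <- pixel_centers(nr, nc, ps)
  out <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    m <- matrix(0, nr, nc)
    for (tr in tracks) {
      d2 <- (ctr$x - tr$x_um[k])^2 + (ctr$y - tr$y_um[k])^2
      m[d2 <= radius_um^2] <- 1
    }
    det <- detect_centroids(label_image(m, ps))
    if (nrow(det) > 0) det$frame <- k - 1L
    out[[k]] <- det
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
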