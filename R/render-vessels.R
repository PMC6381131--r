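#' Render a synthetic planar vessel network
#'
#' Draws a planar graph of thick strokes with exactly `n_junctions`
#' degree->=3 junction points, emulating a 2-D vascular plexus mask.
#' Junction points are placed by rejection sampling with a minimum pairwise
#' separation, connected by their Euclidean minimum spanning tree (which is
#' non-crossing), and short stub branches are added until every junction
#' has degree >= 3. The stroke width is solved from the requested
#' foreground fraction; the exact rendered foreground fraction and the true
#' junction coordinates are returned as ground truth for
#' [branch_points()] / [vascular_density()] recovery.
#'
#' @param n_junctions number of degree->=3 junctions, >= 1.
#' @param target_density requested foreground fraction in (0, 1). The
#'   rendered fraction deviates slightly (stroke overlap at junctions,
#'   rasterization); the recorded `true_density` is exact.
#' @param image_shape_px integer length-2, (rows, cols).
#' @param pixel_size_um um per pixel.
#' @param seed RNG seed.
#' @param max_retries placement retries before declaring the density
#'   unreachable.
#' @return list with `image` (binary [label_image()]), and `ground_truth`:
#'   `branch_points_um` (n x 2 matrix, image-space um), `true_density`
#'   (exact foreground fraction), `stroke_width_um`, `min_separation_um`.
#' @export
render_vessel_network <- function(n_junctions, target_density,
                                  image_shape_px = c(512, 512),
                                  pixel_size_um = 2, seed = 0,
                                  max_retries = 8) {
  if (n_junctions < 1) stop("'n_junctions' must be >= 1", call. = FALSE)
  if (target_density <= 0 || target_density >= 1)
    stop("'target_density' must be in (0, 1)", call. = FALSE)
  nr <- image_shape_px[1]; nc <- image_shape_px[2]
  W <- nc * pixel_size_um; H <- nr * pixel_size_um

  withr::with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      d_min <- 0.8 * min(W, H) / (sqrt(n_junctions) + 1)
      pts <- place_points_min_sep(n_junctions, W, H, d_min,
                                  margin = d_min / 2)
      if (is.null(pts)) next
      segs <- euclidean_mst_segments(pts)
      if (!junction_angles_ok(pts, segs)) next
      segs <- add_junction_stubs(pts, segs, d_min, W, H)
      if (is.null(segs)) next
      total_len <- sum(sqrt((segs[, 3] - segs[, 1])^2 +
                            (segs[, 4] - segs[, 2])^2))
      w <- target_density * W * H / total_len
      # strokes must be drawable yet thin against junction separation and
      # stub length, or thinning erases the branch geometry
      if (w < 2 * pixel_size_um || w > d_min / 8) next
      mask <- rasterize_segments(segs, w, nr, nc, pixel_size_um)
      img <- label_image(mask, pixel_size_um)
      return(list(
        image = img,
        ground_truth = list(branch_points_um = pts,
                            true_density = mean(mask),
                            stroke_width_um = w,
                            min_separation_um = d_min)
      ))
    }
  })
  stop(sprintf(
    "target density %.3f unreachable with %d junctions in a %d x %d field",
    target_density, n_junctions, nr, nc), call. = FALSE)
}

# rejection-sample n points with pairwise separation >= d_min; NULL on failure
place_points_min_sep <- function(n, W, H, d_min, margin, tries = 400) {
  pts <- matrix(NA_real_, n, 2)
  k <- 0
  for (i in seq_len(tries)) {
    p <- c(stats::runif(1, margin, W - margin),
           stats::runif(1, margin, H - margin))
    if (k == 0 || all(sqrt((pts[seq_len(k), 1] - p[1])^2 +
                           (pts[seq_len(k), 2] - p[2])^2) >= d_min)) {
      k <- k + 1
      pts[k, ] <- p
      if (k == n) return(pts)
    }
  }
  NULL
}

# Prim's algorithm on the full distance matrix; returns segments
# (x1, y1, x2, y2) with endpoint indices as attributes
euclidean_mst_segments <- function(pts) {
  n <- nrow(pts)
  if (n == 1) {
    seg <- matrix(numeric(0), 0, 4)
    attr(seg, "ends") <- matrix(integer(0), 0, 2)
    return(seg)
  }
  d <- as.matrix(stats::dist(pts))
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_len(n - 1)) {
    dd <- d[in_tree, !in_tree, drop = FALSE]
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    from <- which(in_tree)[ij[1]]
    to <- which(!in_tree)[ij[2]]
    edges[k, ] <- c(from, to)
    in_tree[to] <- TRUE
  }
  seg <- cbind(pts[edges[, 1], 1], pts[edges[, 1], 2],
               pts[edges[, 2], 1], pts[edges[, 2], 2])
  attr(seg, "ends") <- edges
  seg
}

# MST edges meeting a junction at a shallow angle displace the skeleton
# junction far into the wedge where the strokes overlap; reject layouts
# with incident edges closer than 45 degrees
junction_angles_ok <- function(pts, segs) {
  ends <- attr(segs, "ends")
  for (i in seq_len(nrow(pts))) {
    inc <- incident_angles(pts, ends, segs, i)
    if (length(inc) < 2) next
    for (a in seq_along(inc)[-1]) for (b in seq_len(a - 1)) {
      d <- abs(atan2(sin(inc[a] - inc[b]), cos(inc[a] - inc[b])))
      if (d < pi / 4) return(FALSE)
    }
  }
  TRUE
}

# add stubs so every junction has degree >= 3, avoiding other segments;
# returns augmented segment matrix or NULL if a clear direction cannot
# be found
add_junction_stubs <- function(pts, segs, d_min, W, H) {
  ends <- attr(segs, "ends")
  n <- nrow(pts)
  deg <- tabulate(c(ends), nbins = n)
  all_segs <- segs
  stub_len <- 0.5 * d_min
  for (i in seq_len(n)) {
    while (deg[i] < 3) {
      inc <- incident_angles(pts, ends, all_segs, i)
      dir <- pick_clear_direction(pts[i, ], inc, all_segs, stub_len, W, H,
                                  d_min)
      if (is.null(dir)) return(NULL)
      tip <- pts[i, ] + stub_len * c(cos(dir), sin(dir))
      all_segs <- rbind(all_segs, c(pts[i, 1], pts[i, 2], tip[1], tip[2]))
      ends <- rbind(ends, c(i, NA))
      deg[i] <- deg[i] + 1
    }
  }
  attr(all_segs, "ends") <- ends
  all_segs
}

# directions (radians) of segments incident to junction i
incident_angles <- function(pts, ends, segs, i) {
  out <- numeric(0)
  for (k in seq_len(nrow(segs))) {
    a <- c(segs[k, 1], segs[k, 2]); b <- c(segs[k, 3], segs[k, 4])
    if (sum((a - pts[i, ])^2) < 1e-9) out <- c(out, atan2(b[2] - a[2], b[1] - a[1]))
    else if (sum((b - pts[i, ])^2) < 1e-9) out <- c(out, atan2(a[2] - b[2], a[1] - b[1]))
  }
  out
}

# candidate stub directions sorted by angular clearance from incident
# edges; accept the first whose tip stays in bounds and far from all
# non-incident segments
pick_clear_direction <- function(p, incident, segs, stub_len, W, H, d_min) {
  cand <- seq(0, 2 * pi, length.out = 25)[-25]
  clearance <- vapply(cand, function(a) {
    if (length(incident) == 0) return(pi)
    min(abs(atan2(sin(a - incident), cos(a - incident))))
  }, numeric(1))
  for (a in cand[order(-clearance)]) {
    if (clearance[match(a, cand)] < pi / 3) break
    tip <- p + stub_len * c(cos(a), sin(a))
    if (any(tip < d_min / 4) || tip[1] > W - d_min / 4 || tip[2] > H - d_min / 4) next
    ok <- TRUE
    for (k in seq_len(nrow(segs))) {
      a1 <- segs[k, 1:2]; b1 <- segs[k, 3:4]
      if (sum((a1 - p)^2) < 1e-9 || sum((b1 - p)^2) < 1e-9) next
      if (segment_segment_distance(p, tip, a1, b1) < 0.3 * d_min) {
        ok <- FALSE; break
      }
    }
    if (ok) return(a)
  }
  NULL
}

# minimum distance between two segments (0 if they cross)
segment_segment_distance <- function(a1, b1, a2, b2) {
  d1 <- b1 - a1; d2 <- b2 - a2
  cross <- function(u, v) u[1] * v[2] - u[2] * v[1]
  den <- cross(d1, d2)
  if (abs(den) > 1e-12) {
    t <- cross(a2 - a1, d2) / den
    u <- cross(a2 - a1, d1) / den
    if (t >= 0 && t <= 1 && u >= 0 && u <= 1) return(0)
  }
  min(point_segment_distance(a1, a2, b2), point_segment_distance(b1, a2, b2),
      point_segment_distance(a2, a1, b1), point_segment_distance(b2, a1, b1))
}

point_segment_distance <- function(q, a, b) {
  ab <- b - a
  t <- sum((q - a) * ab) / max(sum(ab^2), 1e-12)
  t <- min(1, max(0, t))
  sqrt(sum((a + t * ab - q)^2))
}

# binary mask: pixel centres within w/2 of any segment
rasterize_segments <- function(segs, w, nr, nc, pixel_size_um) {
  ctr <- pixel_centers(nr, nc, pixel_size_um)
  mask <- matrix(0, nr, nc)
  r <- w / 2
  for (k in seq_len(nrow(segs))) {
    a <- segs[k, 1:2]; b <- segs[k, 3:4]
    # bounding box cull for speed
    lo_x <- min(a[1], b[1]) - r; hi_x <- max(a[1], b[1]) + r
    lo_y <- min(a[2], b[2]) - r; hi_y <- max(a[2], b[2]) + r
    cols <- which(ctr$x[1, ] >= lo_x & ctr$x[1, ] <= hi_x)
    rows <- which(ctr$y[, 1] >= lo_y & ctr$y[, 1] <= hi_y)
    if (!length(cols) || !length(rows)) next
    px <- ctr$x[rows, cols, drop = FALSE]
    py <- ctr$y[rows, cols, drop = FALSE]
    ab <- b - a
    len2 <- max(sum(ab^2), 1e-12)
    t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2
    t[t < 0] <- 0; t[t > 1] <- 1
    d2 <- (a[1] + t * ab[1] - px)^2 + (a[2] + t * ab[2] - py)^2
    sub <- mask[rows, cols, drop = FALSE]
    sub[d2 <= r^2] <- 1
    mask[rows, cols] <- sub
  }
  mask
}
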