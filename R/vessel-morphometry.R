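#' Vascular density
#'
#' Foreground (vessel) pixel area inside the region of interest divided by
#' the ROI area, as a percentage.
#'
#' @param mask binary single-channel [label_image()].
#' @param roi a [roi_rect()] in um, or NULL for the whole image.
#' @return percentage in [0, 100].
#' @export
vascular_density <- function(mask, roi = NULL) {
  px <- as_binary_matrix(mask)
  sel <- roi_pixel_mask(mask, roi)
  if (!any(sel)) stop("roi contains no pixels", call. = FALSE)
  sum(px[sel]) / sum(sel) * 100
}

#' Morphological skeleton (Zhang-Suen thinning)
#'
#' Iterative thinning of a binary mask to a 1-px-wide, 8-connected
#' skeleton. Implemented with vectorized neighbourhood shifts; border
#' pixels are treated as background.
#'
#' @param mask binary matrix or single-channel [label_image()].
#' @return binary matrix of the same size.
#' @export
skeletonize <- function(mask) {
  m <- if (inherits(mask, "label_image")) as_binary_matrix(mask) else mask
  storage.mode(m) <- "integer"
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  shift <- function(p, dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad[2:(nr + 1), 2:(nc + 1)]
      # neighbours clockwise from north
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1); p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1); p6 <- shift(pad, 1, 0); p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- if (step == 1) {
        p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- p == 1 & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        changed <- TRUE
        p[del] <- 0L
        pad[2:(nr + 1), 2:(nc + 1)] <- p
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1), 2:(nc + 1)]
}

# count of 8-connected skeleton neighbours at each skeleton pixel
skeleton_neighbor_counts <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- skel
  nb <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  nb * skel
}

# arcs of a binary image crossing the Chebyshev ring of the given radius
# around a pixel, restricted to the component connected to that pixel
# within the window. Used on the vessel MASK (not the skeleton): around a
# true junction a ring wider than the stroke crosses >= 3 stroke arcs,
# while along a plain stroke it crosses exactly 2 — a classification that
# is immune to the displacement/merge artifacts of morphological thinning.
ring_arc_count <- function(img, r0, c0, radius = 3L) {
  nr <- nrow(img); nc <- ncol(img)
  half <- radius + 2L
  win <- matrix(0L, 2 * half + 1, 2 * half + 1)
  rows <- (r0 - half):(r0 + half)
  cols <- (c0 - half):(c0 + half)
  ok_r <- rows >= 1 & rows <= nr
  ok_c <- cols >= 1 & cols <= nc
  win[ok_r, ok_c] <- img[rows[ok_r], cols[ok_c]]
  lab <- label_components8(win)
  keep <- lab == lab[half + 1, half + 1]
  # Euclidean annulus of width 3 px around the centre
  dr <- row(win) - (half + 1)
  dc <- col(win) - (half + 1)
  d <- sqrt(dr^2 + dc^2)
  on_ring <- keep & d >= radius - 1.5 & d <= radius + 1.5
  if (!any(on_ring)) return(0L)
  ang <- sort(atan2(dr[on_ring], dc[on_ring]))
  n <- length(ang)
  # angular gaps wider than ~2 px of arc separate distinct stroke arcs;
  # an arc must hold >= 3 annulus cells, so stray fringe cells (corners of
  # stroke caps grazing the annulus) do not register as branches
  gap_after <- c(diff(ang), ang[1] + 2 * pi - ang[n]) > 2.2 / radius
  if (!any(gap_after)) return(1L)
  # walk the circle starting just after the last gap; arcs are runs
  # between gaps
  start <- (which(gap_after)[sum(gap_after)] %% n) + 1
  sizes <- integer(0)
  run <- 0L
  for (i in ((start - 1 + 0:(n - 1)) %% n) + 1) {
    run <- run + 1L
    if (gap_after[i]) {
      sizes <- c(sizes, run)
      run <- 0L
    }
  }
  max(sum(sizes >= 3), 1L)
}


#' Count vessel branch points
#'
#' Skeletonizes the mask and marks as junction pixels those skeleton
#' pixels around which the vessel mask crosses a ring (of radius
#' `merge_radius_um`, about twice the stroke width) in three or more
#' distinct arcs: a plain stroke crosses such a ring twice, a branching
#' stroke three or more times. Scoring arcs of the mask rather than of the
#' skeleton makes the count immune to the junction displacement and
#' tangential-merge artifacts of morphological thinning. Junction pixels
#' within `merge_radius_um` merge into single branch points
#' (single-linkage clustering); the count covers merged points whose
#' centroid lies in the ROI. Reliable when junctions are separated by at
#' least about five stroke widths, the regime of the assay.
#'
#' @param mask binary single-channel [label_image()].
#' @param roi a [roi_rect()] or NULL for the whole image.
#' @param merge_radius_um merge radius, um; sensible default is about twice
#'   the stroke (vessel) width.
#' @return list with `count` and `points_um` (n x 2 centroid matrix).
#' @export
branch_points <- function(mask, roi = NULL, merge_radius_um = 10) {
  px <- as_binary_matrix(mask)
  ps <- mask$pixel_size_um
  if (!any(px == 1)) return(list(count = 0L, points_um = matrix(0, 0, 2)))
  skel <- skeletonize(px)
  cand <- which(skel == 1, arr.ind = TRUE)
  radius <- max(3L, as.integer(round(merge_radius_um / ps)))
  arcs <- vapply(seq_len(nrow(cand)), function(i) {
    ring_arc_count(px, cand[i, 1], cand[i, 2], radius = radius)
  }, numeric(1))
  jr <- cand[arcs >= 3, , drop = FALSE]
  if (nrow(jr) == 0) return(list(count = 0L, points_um = matrix(0, 0, 2)))
  pts <- cbind((jr[, 2] - 1) * ps, (jr[, 1] - 1) * ps)  # (x, y) um
  cl <- if (nrow(pts) == 1) 1L else {
    stats::cutree(stats::hclust(stats::dist(pts), method = "single"),
                  h = merge_radius_um)
  }
  cent <- do.call(rbind, lapply(split(seq_len(nrow(pts)), cl), function(ix) {
    colMeans(pts[ix, , drop = FALSE])
  }))
  if (!is.null(roi)) {
    keep <- cent[, 1] >= roi$x & cent[, 1] < roi$x + roi$width &
      cent[, 2] >= roi$y & cent[, 2] < roi$y + roi$height
    cent <- cent[keep, , drop = FALSE]
  }
  list(count = nrow(cent), points_um = cent)
}

#' Radial outgrowth of a vascular mask
#'
#' Splits the plane into `n_sectors` equal angular sectors around the
#' centre (the optic-disc position), takes the maximum centre-to-foreground
#' distance per sector (the vascular front of each leaflet), and returns
#' the sector mean. Sectors containing no foreground are excluded with a
#' warning.
#'
#' @param mask binary single-channel [label_image()].
#' @param center_um length-2 centre in um (image space); must be inside
#'   the image.
#' @param n_sectors number of equal sectors (default 4 leaflets).
#' @return mean front distance in um, with attribute `per_sector_um`.
#' @export
radial_outgrowth <- function(mask, center_um, n_sectors = 4) {
  px <- as_binary_matrix(mask)
  ps <- mask$pixel_size_um
  if (!any(px == 1)) stop("empty mask", call. = FALSE)
  d <- dim(px)
  if (any(center_um < 0) || center_um[1] > d[2] * ps || center_um[2] > d[1] * ps)
    stop("'center_um' must lie inside the image", call. = FALSE)
  rows <- row(px)[px == 1]; cols <- col(px)[px == 1]
  dx <- (cols - 1) * ps - center_um[1]
  dy <- (rows - 1) * ps - center_um[2]
  dist <- sqrt(dx^2 + dy^2)
  ang <- wrap_angle(rad2deg(atan2(-dy, dx)))   # y-up convention
  sec <- pmin(floor(ang / (360 / n_sectors)) + 1, n_sectors)
  per <- vapply(seq_len(n_sectors), function(s) {
    if (!any(sec == s)) NA_real_ else max(dist[sec == s])
  }, numeric(1))
  if (anyNA(per))
    warning(sprintf("%d empty sector(s) excluded from the mean",
                    sum(is.na(per))))
  structure(mean(per, na.rm = TRUE), per_sector_um = per)
}

#' Sprout and filopodia counts along the angiogenic front
#'
#' Normalizes annotated sprout/filopodium counts to a 100-um front length
#' and reports filopodia per sprout.
#'
#' @param annotations data.frame with a `label` column containing
#'   `"sprout"` / `"filopodium"` entries (other labels ignored).
#' @param front_length_um measured angiogenic front length, um, > 0.
#' @return list with `sprouts_per_100um`, `filopodia_per_100um`,
#'   `filopodia_per_sprout` (NA with flag `"no_sprouts"` when undefined),
#'   `n_sprouts`, `n_filopodia`.
#' @export
front_counts <- function(annotations, front_length_um) {
  stopifnot(is.data.frame(annotations), "label" %in% names(annotations))
  if (front_length_um <= 0) stop("'front_length_um' must be > 0", call. = FALSE)
  ns <- sum(annotations$label == "sprout")
  nf <- sum(annotations$label == "filopodium")
  fps <- if (ns == 0 && nf > 0) NA_real_ else if (ns == 0) 0 else nf / ns
  list(sprouts_per_100um = ns * 100 / front_length_um,
       filopodia_per_100um = nf * 100 / front_length_um,
       filopodia_per_sprout = fps,
       flag = if (ns == 0 && nf > 0) "no_sprouts" else "ok",
       n_sprouts = ns, n_filopodia = nf)
}

#' Two-mask area-fraction metrics
#'
#' `mode = "leakage"`: area of `mask_a` outside `mask_b` (e.g. RBC stain
#' outside vessels) divided by the ROI area, as a percentage.
#' `mode = "tuft"`: area of `mask_a` (e.g. neovascular tufts) divided by
#' the area of `mask_b` (total vessel mask), as a percentage.
#'
#' @param mask_a,mask_b aligned binary [label_image()]s.
#' @param roi a [roi_rect()] or NULL (leakage mode only).
#' @param mode `"leakage"` or `"tuft"`.
#' @return percentage (>= 0; leakage is <= 100).
#' @export
area_fraction_metrics <- function(mask_a, mask_b, roi = NULL,
                                  mode = c("leakage", "tuft")) {
  mode <- match.arg(mode)
  a <- as_binary_matrix(mask_a, "mask_a")
  b <- as_binary_matrix(mask_b, "mask_b")
  if (!all(dim(a) == dim(b))) stop("masks must be aligned", call. = FALSE)
  if (mode == "leakage") {
    sel <- roi_pixel_mask(mask_a, roi)
    if (!any(sel)) stop("roi contains no pixels", call. = FALSE)
    return(sum(a[sel] == 1 & b[sel] == 0) / sum(sel) * 100)
  }
  denom <- sum(b)
  if (denom == 0) stop("mask_b has zero area", call. = FALSE)
  sum(a) / denom * 100
}

#' Background-subtracted, control-normalized staining intensity
#'
#' Mean intensity over the vessel ROIs minus the mean over the background
#' (non-vascularized) ROIs, clipped at zero, divided by the control mean —
#' the standard fold-change readout for staining intensity.
#'
#' @param image single-channel intensity [label_image()].
#' @param vessel_rois list of [roi_rect()] over vessels (conventionally
#'   ten).
#' @param background_rois list of [roi_rect()] over non-vascularized areas.
#' @param control_mean background-subtracted mean of the control group,
#'   > 0.
#' @return fold change >= 0, with attribute `flag` (`"ok"` or
#'   `"background_exceeds_signal"`).
#' @export
normalized_intensity <- function(image, vessel_rois, background_rois,
                                 control_mean) {
  stopifnot(inherits(image, "label_image"), is.list(vessel_rois),
            is.list(background_rois))
  if (control_mean <= 0) stop("'control_mean' must be > 0", call. = FALSE)
  px <- image$pixels
  if (!is.matrix(px)) stop("'image' must be single-channel", call. = FALSE)
  roi_mean <- function(r) mean(px[roi_pixel_mask(image, r)])
  bg <- mean(vapply(background_rois, roi_mean, numeric(1)))
  signal <- vapply(vessel_rois, roi_mean, numeric(1)) - bg
  val <- mean(pmax(signal, 0)) / control_mean
  flag <- if (all(signal <= 0)) "background_exceeds_signal" else "ok"
  structure(val, flag = flag)
}
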