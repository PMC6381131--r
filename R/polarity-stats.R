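#' Fit nuclear shape from a binary mask
#'
#' Orientation comes from the principal axis of the second central moments
#' of the pixel-centre cloud (with the per-pixel variance term, so small
#' shapes are not biased). Height is the caliper extent of the mask along
#' the long axis and Width is the minimum caliper extent over all
#' orientations; for elliptical shapes the minimum coincides with the
#' extent perpendicular to the long axis, i.e. the classic
#' Height (long-axis length) over Width (maximum perpendicular extent)
#' readout, and ellipticity = Height / Width is always >= 1. When the
#' second moments are isotropic (circle, square) the principal axis is
#' undefined; the orientation then falls back to the direction of maximum
#' caliper extent (smallest such angle wins).
#'
#' @param mask binary single-channel [label_image()] containing exactly one
#'   connected component of >= 20 px.
#' @return a [nucleus_shape()] (centroid in image-space um, orientation in
#'   the mathematical y-up convention).
#' @export
fit_nucleus <- function(mask) {
  px <- as_binary_matrix(mask)
  ps <- mask$pixel_size_um
  lab <- label_components8(px)
  n_comp <- max(lab)
  if (n_comp == 0) stop("empty mask", call. = FALSE)
  if (n_comp > 1) stop("mask must contain a single connected component",
                       call. = FALSE)
  if (sum(px) < 20) stop("component too small (< 20 px)", call. = FALSE)

  rows <- row(px)[px == 1]; cols <- col(px)[px == 1]
  x <- (cols - 1) * ps
  y <- -(rows - 1) * ps          # flip to y-up mathematical convention
  cx <- mean(x); cy <- mean(y)
  dx <- x - cx; dy <- y - cy
  # second central moments + per-pixel square variance
  m20 <- mean(dx^2) + ps^2 / 12
  m02 <- mean(dy^2) + ps^2 / 12
  m11 <- mean(dx * dy)

  anis <- sqrt((m20 - m02)^2 + 4 * m11^2) / (m20 + m02)
  grid <- seq(0, 179.5, by = 0.5)
  extents <- caliper_extents(dx, dy, grid, ps)
  orientation <- if (anis < 1e-3) {
    grid[which.max(extents)]     # isotropic moments: max-caliper fallback
  } else {
    wrap_axial(rad2deg(0.5 * atan2(2 * m11, m20 - m02)))
  }
  height <- caliper_extents(dx, dy, orientation, ps)
  width <- min(extents)
  if (width < 1.5 * ps) stop("degenerate (line-like) component", call. = FALSE)
  width <- min(width, height)
  nucleus_shape(centroid_um = c(cx, -cy),   # back to image-space y
                height_um = height, width_um = width,
                orientation_deg = orientation)
}

# caliper extent of the pixel cloud along each direction (degrees),
# approximating pixels as unit squares by adding one pixel size
caliper_extents <- function(dx, dy, theta_deg, ps) {
  vapply(theta_deg, function(th) {
    t <- deg2rad(th)
    p <- dx * cos(t) + dy * sin(t)
    max(p) - min(p) + ps
  }, numeric(1))
}

#' Nuclear long-axis angle projected into the first quadrant
#'
#' Folds an axial nuclear orientation into [0, 90] relative to the
#' migration (filopodia-extension) direction: a long axis aligned with the
#' migration direction maps to 90 degrees and one lying along the scratch
#' (perpendicular to migration) maps to 0.
#'
#' @param orientation_deg axial orientation(s) of the nuclear long axis,
#'   degrees (mod 180).
#' @param reference_deg migration/filopodia direction, degrees.
#' @return angle(s) in [0, 90].
#' @export
nuclear_angle_first_quadrant <- function(orientation_deg, reference_deg) {
  90 - axial_distance(orientation_deg, reference_deg)
}

#' Organelle polarization angle
#'
#' The direction of the vector from the nucleus centre to the organelle
#' (Golgi apparatus, MTOC, pericentrin), measured counter-clockwise from
#' the reference direction (0 degrees = reference, typically the migration
#' direction). Centroids are in image-space um (y down); the angle is
#' computed in the mathematical y-up convention.
#'
#' @param nucleus a [nucleus_shape()] or a length-2 centroid in um.
#' @param organelle_centroid_um length-2 organelle centre, um.
#' @param reference_deg reference direction, degrees (default 0).
#' @return angle in [0, 360).
#' @export
organelle_polarization_angle <- function(nucleus, organelle_centroid_um,
                                         reference_deg = 0) {
  c0 <- if (inherits(nucleus, "nucleus_shape")) nucleus$centroid_um
        else as.numeric(nucleus)
  v <- as.numeric(organelle_centroid_um) - c0
  if (sqrt(sum(v^2)) < 1e-12)
    stop("organelle coincides with the nucleus centre", call. = FALSE)
  wrap_angle(unit_to_angle(c(v[1], -v[2])) - reference_deg)
}

#' Fraction of polarized cells
#'
#' Sector statistic on organelle polarization angles: the fraction within
#' the `width_deg` window centred on `center_deg`. With
#' `front_rear = TRUE` an angle counts when it falls within the window
#' around the centre **or** around the antipode (centre + 180), the
#' "polarized towards the anterior or posterior of the nucleus" readout.
#'
#' @param angles_deg organelle polarization angles, degrees.
#' @param center_deg sector centre (default 0 = migration direction).
#' @param width_deg sector width (default 120).
#' @param front_rear logical; accept the antipodal sector too.
#' @return fraction in [0, 1].
#' @export
polarized_fraction <- function(angles_deg, center_deg = 0, width_deg = 120,
                               front_rear = FALSE) {
  if (!front_rear)
    return(as.numeric(sector_fraction(angles_deg, center_deg, width_deg)))
  if (width_deg <= 0 || width_deg > 360)
    stop("'width_deg' must be in (0, 360]", call. = FALSE)
  if (length(angles_deg) == 0) stop("empty angle list", call. = FALSE)
  use <- angles_deg[!is.na(angles_deg)]
  mean(angle_distance(use, center_deg) <= width_deg / 2 |
         angle_distance(use, center_deg + 180) <= width_deg / 2)
}

#' Measure polarity from a rendered nucleus/organelle image
#'
#' Full measurement pipeline on a two-channel label image: label nuclei,
#' fit each nuclear shape, detect organelle blobs, assign each organelle to
#' the nearest nucleus centroid, and report per-cell polarity measurements.
#'
#' @param image a [label_image()] with `nucleus` and `organelle` channels
#'   (e.g. from [render_polarity_image()]).
#' @param reference_deg reference (migration) direction, degrees.
#' @param min_area_px minimum object area for both channels (default 5).
#' @return data.frame with one row per nucleus: `cell_id`, `x_um`, `y_um`,
#'   `height_um`, `width_um`, `ellipticity`, `orientation_deg`,
#'   `nuclear_angle_q1_deg`, `organelle_angle_deg` (NA when no organelle
#'   was assigned).
#' @export
measure_polarity_image <- function(image, reference_deg = 0,
                                   min_area_px = 5) {
  nuc_ch <- get_channel(image, "nucleus")
  org_ch <- get_channel(image, "organelle")
  ps <- image$pixel_size_um
  lab <- label_components8(nuc_ch$pixels)
  n <- max(lab)
  if (n == 0)
    return(data.frame(cell_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), height_um = numeric(0),
                      width_um = numeric(0), ellipticity = numeric(0),
                      orientation_deg = numeric(0),
                      nuclear_angle_q1_deg = numeric(0),
                      organelle_angle_deg = numeric(0)))
  shapes <- lapply(seq_len(n), function(i) {
    fit_nucleus(label_image(matrix(as.numeric(lab == i), nrow(lab), ncol(lab)),
                            ps))
  })
  orgs <- detect_centroids(org_ch, min_area_px = min_area_px)
  assigned <- rep(NA_real_, n)
  if (nrow(orgs) > 0) {
    centers <- t(vapply(shapes, function(s) s$centroid_um, numeric(2)))
    for (j in seq_len(nrow(orgs))) {
      oc <- c(orgs$x_px[j], orgs$y_px[j]) * ps
      i <- which.min((centers[, 1] - oc[1])^2 + (centers[, 2] - oc[2])^2)
      assigned[i] <- organelle_polarization_angle(shapes[[i]], oc,
                                                  reference_deg)
    }
  }
  data.frame(
    cell_id = seq_len(n),
    x_um = vapply(shapes, function(s) s$centroid_um[1], numeric(1)),
    y_um = vapply(shapes, function(s) s$centroid_um[2], numeric(1)),
    height_um = vapply(shapes, function(s) s$height_um, numeric(1)),
    width_um = vapply(shapes, function(s) s$width_um, numeric(1)),
    ellipticity = vapply(shapes, function(s) s$ellipticity, numeric(1)),
    orientation_deg = vapply(shapes, function(s) s$orientation_deg, numeric(1)),
    nuclear_angle_q1_deg = nuclear_angle_first_quadrant(
      vapply(shapes, function(s) s$orientation_deg, numeric(1)), reference_deg),
    organelle_angle_deg = assigned
  )
}
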