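#' Render a nucleus/organelle polarity image
#'
#' Draws each nucleus as a hard (un-anti-aliased) filled ellipse and each
#' organelle (Golgi/MTOC stand-in) as a small disc at a known angle and
#' distance from its nucleus centroid, emulating a two-channel
#' nucleus/Golgi staining. Hard binary rendering keeps moment-based shape
#' recovery analytically predictable. An optional Gaussian noise channel
#' carries intensity noise; masks are never noised.
#'
#' @param nuclei list of [nucleus_shape()] (centroids in um, image space,
#'   y down for placement; orientations in the mathematical y-up
#'   convention).
#' @param organelle_angles_deg one angle per nucleus, degrees
#'   counter-clockwise (y-up convention) from the reference direction
#'   (`reference_deg`).
#' @param organelle_distance_um distance from nucleus centroid to organelle
#'   centre, um.
#' @param image_shape_px integer length-2, (rows, cols).
#' @param pixel_size_um um per pixel.
#' @param seed RNG seed for the noise channel.
#' @param organelle_radius_um organelle disc radius, um (default 1.5).
#' @param noise_sd additive Gaussian noise SD on the noise channel
#'   (default 0).
#' @param reference_deg reference direction for the organelle angles
#'   (default 0, i.e. +x).
#' @return 3-channel [label_image()] with channels
#'   `nucleus`, `organelle`, `noise`.
#' @export
render_polarity_image <- function(nuclei, organelle_angles_deg,
                                  organelle_distance_um,
                                  image_shape_px = c(256, 256),
                                  pixel_size_um = 0.5, seed = 0,
                                  organelle_radius_um = 1.5,
                                  noise_sd = 0, reference_deg = 0) {
  stopifnot(is.list(nuclei))
  if (length(organelle_angles_deg) != length(nuclei))
    stop("one organelle angle per nucleus required", call. = FALSE)
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be > 0", call. = FALSE)
  nr <- image_shape_px[1]; nc <- image_shape_px[2]
  ext <- c(nc, nr) * pixel_size_um
  ctr <- pixel_centers(nr, nc, pixel_size_um)

  nuc <- matrix(0, nr, nc)
  org <- matrix(0, nr, nc)
  for (i in seq_along(nuclei)) {
    sh <- nuclei[[i]]
    stopifnot(inherits(sh, "nucleus_shape"))
    if (any(sh$centroid_um - sh$height_um / 2 < 0) ||
        sh$centroid_um[1] + sh$height_um / 2 > ext[1] ||
        sh$centroid_um[2] + sh$height_um / 2 > ext[2])
      stop(sprintf("nucleus %d does not fit within image bounds", i),
           call. = FALSE)
    th <- deg2rad(sh$orientation_deg)
    dx <- ctr$x - sh$centroid_um[1]
    dy <- ctr$y - sh$centroid_um[2]
    # y-down image space: major axis (cos, -sin), minor (-sin, -cos)
    pj1 <- dx * cos(th) - dy * sin(th)
    pj2 <- -dx * sin(th) - dy * cos(th)
    inside <- (pj1 / (sh$height_um / 2))^2 + (pj2 / (sh$width_um / 2))^2 <= 1
    if (any(nuc[inside] == 1))
      warning(sprintf("nucleus %d overlaps a previously drawn nucleus", i))
    nuc[inside] <- 1

    a <- deg2rad(reference_deg + organelle_angles_deg[i])
    oc <- sh$centroid_um + organelle_distance_um * c(cos(a), -sin(a))
    d2 <- (ctr$x - oc[1])^2 + (ctr$y - oc[2])^2
    org[d2 <= organelle_radius_um^2] <- 1
  }
  noise <- withr::with_seed(seed, matrix(stats::rnorm(nr * nc, sd = noise_sd),
                                         nr, nc))
  label_image(array(c(nuc, org, noise), dim = c(nr, nc, 3)), pixel_size_um,
              channels = c("nucleus", "organelle", "noise"))
}

#' Render a scratch-wound mask time series
#'
#' Binary monolayer masks with a vertical gap whose width decreases
#' linearly at `closure_rate_um_min`, both margins advancing symmetrically,
#' clipped at full closure. Frame times follow the simulation config
#' (default 91 frames at 10 min).
#'
#' @param initial_width_um starting gap width, um; must be > 0 and fit in
#'   the arena.
#' @param closure_rate_um_min linear closure rate, um/min, >= 0.
#' @param config a [simulation_config()] supplying `n_frames`,
#'   `frame_interval_min` and `arena_um`.
#' @param pixel_size_um raster resolution, um/pixel (default 2).
#' @return list of binary [label_image()] masks (1 = monolayer), each with
#'   attribute `t_min`.
#' @export
render_wound_series <- function(initial_width_um, closure_rate_um_min,
                                config, pixel_size_um = 2) {
  stopifnot(inherits(config, "simulation_config"))
  if (initial_width_um <= 0) stop("'initial_width_um' must be > 0", call. = FALSE)
  if (closure_rate_um_min < 0) stop("'closure_rate_um_min' must be >= 0", call. = FALSE)
  if (initial_width_um > config$arena_um[1])
    stop("gap wider than the arena", call. = FALSE)
  nc <- round(config$arena_um[1] / pixel_size_um)
  nr <- round(config$arena_um[2] / pixel_size_um)
  xs <- (seq_len(nc) - 1) * pixel_size_um
  cx <- config$arena_um[1] / 2
  lapply(seq_len(config$n_frames), function(k) {
    t <- (k - 1) * config$frame_interval_min
    w <- max(0, initial_width_um - closure_rate_um_min * t)
    in_gap <- abs(xs - cx) < w / 2
    im <- label_image(matrix(rep(as.numeric(!in_gap), each = nr), nr, nc),
                      pixel_size_um)
    attr(im, "t_min") <- t
    im
  })
}
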