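#' Per-cell migration statistics
#'
#' Summarizes one trajectory in the wound reference frame: total migrated
#' path, net displacement, average speed (path length over elapsed time),
#' directional persistence (net displacement divided by total path),
#' instantaneous speeds and distance from origin on a coarser sampling grid
#' (default every 30 min), and the displacement angle measured
#' counter-clockwise from the migration direction (0 degrees).
#'
#' @param track a [trajectory()].
#' @param wound a [wound_geometry()].
#' @param sampling_interval_min grid for instantaneous speed / distance from
#'   origin, minutes (default 30). Samples snap to the nearest frame when
#'   the grids misalign.
#' @return list of class `"migration_summary"` with fields `track_id`,
#'   `total_path_um`, `net_displacement_um`, `average_speed_um_min`,
#'   `displacement_speed_um_min` (net displacement over elapsed time),
#'   `persistence`, `persistence_flag` (`"ok"` or `"zero_path"`),
#'   `displacement_angle_deg` (NA for zero net displacement),
#'   `instantaneous_speeds_um_min`, `distance_from_origin_um`,
#'   `sample_times_min`.
#' @export
summarize_track <- function(track, wound, sampling_interval_min = 30) {
  stopifnot(inherits(track, "trajectory"), inherits(wound, "wound_geometry"))
  n <- nrow(track)
  if (n < 2) stop("trajectory needs at least 2 samples", call. = FALSE)
  if (sampling_interval_min <= 0)
    stop("'sampling_interval_min' must be > 0", call. = FALSE)
  p <- cbind(track$x_um, track$y_um)
  steps <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-n, , drop = FALSE])^2))
  total_path <- sum(steps)
  disp <- p[n, ] - p[1, ]
  net <- sqrt(sum(disp^2))
  elapsed <- track$t_min[n] - track$t_min[1]

  zero_path <- total_path <= 0
  persistence <- if (zero_path) 0 else net / total_path

  angle <- if (net > 0) {
    wrap_angle(unit_to_angle(disp) - wound$migration_angle_deg)
  } else NA_real_

  # coarse grid: nearest frame to each multiple of the sampling interval
  grid <- seq(track$t_min[1], track$t_min[n], by = sampling_interval_min)
  idx <- vapply(grid, function(t) which.min(abs(track$t_min - t)), integer(1))
  idx <- idx[!duplicated(idx)]
  gp <- p[idx, , drop = FALSE]
  gt <- track$t_min[idx]
  inst <- if (length(idx) >= 2) {
    sqrt(rowSums((gp[-1, , drop = FALSE] -
                  gp[-length(idx), , drop = FALSE])^2)) / diff(gt)
  } else numeric(0)
  dfo <- sqrt(rowSums((gp - matrix(p[1, ], nrow = length(idx), ncol = 2,
                                   byrow = TRUE))^2))

  structure(
    list(track_id = track$track_id[1],
         total_path_um = total_path,
         net_displacement_um = net,
         average_speed_um_min = total_path / elapsed,
         displacement_speed_um_min = net / elapsed,
         persistence = persistence,
         persistence_flag = if (zero_path) "zero_path" else "ok",
         displacement_angle_deg = angle,
         instantaneous_speeds_um_min = inst,
         distance_from_origin_um = dfo,
         sample_times_min = gt),
    class = "migration_summary"
  )
}

#' Fraction of angles inside an angular sector
#'
#' The sector statistic used on polar plots of displacement or organelle
#' angles: the fraction of angles within `width/2` degrees (circular
#' distance, boundary inclusive) of the sector centre. The conventional
#' scoring window is the 120-degree sector centred on the migration
#' direction (the vector perpendicular to the scratch).
#'
#' @param angles_deg numeric vector of angles in degrees; NA entries
#'   (undefined angles of zero-displacement cells) are excluded from the
#'   count but the returned attribute `n_total` includes them.
#' @param center_deg sector centre in degrees.
#' @param width_deg sector width in (0, 360], default 120.
#' @return fraction in [0, 1] of non-NA angles inside the sector, with
#'   attributes `n_inside`, `n_used`, `n_total`.
#' @examples
#' sector_fraction(c(0, 60, 120, 180, 240, 300), center = 0)  # 0.5
#' @export
sector_fraction <- function(angles_deg, center_deg = 0, width_deg = 120) {
  if (width_deg <= 0 || width_deg > 360)
    stop("'width_deg' must be in (0, 360]", call. = FALSE)
  if (length(angles_deg) == 0) stop("empty angle list", call. = FALSE)
  use <- angles_deg[!is.na(angles_deg)]
  if (length(use) == 0) stop("all angles are NA", call. = FALSE)
  inside <- angle_distance(use, center_deg) <= width_deg / 2
  structure(mean(inside),
            n_inside = sum(inside), n_used = length(use),
            n_total = length(angles_deg))
}

#' Wound closure percentage and rate
#'
#' Closure percent at each time is `(W0 - W_t) / W0 * 100`; the closure rate
#' in um/min is the width difference between the first and last time points
#' divided by the elapsed minutes (900 for the standard 15-h assay).
#'
#' @param t_min times in minutes, first must be 0, strictly increasing.
#' @param width_um wound widths in um, non-negative.
#' @return list with `closure_percent` (vector aligned with `t_min`) and
#'   `closure_rate_um_min`.
#' @examples
#' wound_closure(c(0, 900), c(1000, 50))  # 95% closure, rate ~1.056 um/min
#' @export
wound_closure <- function(t_min, width_um) {
  if (length(t_min) != length(width_um) || length(t_min) < 2)
    stop("need matched time/width series of length >= 2", call. = FALSE)
  stop_if_not_finite(t_min, "t_min"); stop_if_not_finite(width_um, "width_um")
  if (t_min[1] != 0) stop("first time must be 0", call. = FALSE)
  if (any(diff(t_min) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(width_um < 0)) stop("widths must be non-negative", call. = FALSE)
  w0 <- width_um[1]
  if (w0 == 0) stop("initial width is 0: closure undefined", call. = FALSE)
  n <- length(width_um)
  list(closure_percent = (w0 - width_um) / w0 * 100,
       closure_rate_um_min = (w0 - width_um[n]) / t_min[n])
}

#' Population summary of migration statistics
#'
#' Aggregates per-cell summaries: mean/median/SD of each scalar metric plus
#' the sector fraction of displacement angles in the 120-degree window
#' centred on the migration direction. Zero-displacement cells (undefined
#' angle) are counted in `n` but excluded from the sector count.
#'
#' @param summaries list of [summarize_track()] results.
#' @param wound a [wound_geometry()].
#' @param sector_width_deg scoring sector width, default 120.
#' @return list with `metrics` (data.frame metric/mean/median/sd),
#'   `sector_fraction`, `displacement_angles_deg`, `n`, `n_zero_displacement`.
#' @export
population_summary <- function(summaries, wound, sector_width_deg = 120) {
  stopifnot(length(summaries) >= 1, inherits(wound, "wound_geometry"))
  grab <- function(f) vapply(summaries, function(s) s[[f]], numeric(1))
  fields <- c("average_speed_um_min", "displacement_speed_um_min",
              "net_displacement_um", "total_path_um", "persistence")
  metrics <- do.call(rbind, lapply(fields, function(f) {
    v <- grab(f)
    data.frame(metric = f, mean = mean(v), median = stats::median(v),
               sd = stats::sd(v))
  }))
  angles <- vapply(summaries, function(s) s$displacement_angle_deg, numeric(1))
  # angles are already relative to the migration direction (0 deg)
  sf <- sector_fraction(angles, center_deg = 0, width_deg = sector_width_deg)
  list(metrics = metrics, sector_fraction = as.numeric(sf),
       displacement_angles_deg = angles,
       n = length(summaries), n_zero_displacement = sum(is.na(angles)))
}

#' Measure wound width on a binary monolayer mask
#'
#' Width is the mean, over rows intersecting the gap, of the background run
#' between the two cell margins (a mean is used rather than a minimum for
#' robustness to mask noise). The gap is assumed vertical in image space
#' (columns = migration axis).
#'
#' @param mask a binary single-channel [label_image()] (1 = monolayer).
#' @return width in um (0 if no row shows a gap).
#' @export
wound_width <- function(mask) {
  px <- as_binary_matrix(mask)
  gaps <- apply(px, 1, function(row) {
    fg <- which(row == 1)
    if (length(fg) < 2) return(NA_real_)
    inner <- sum(row[fg[1]:fg[length(fg)]] == 0)
    if (inner == 0) NA_real_ else inner
  })
  gaps <- gaps[!is.na(gaps)]
  if (length(gaps) == 0) return(0)
  mean(gaps) * mask$pixel_size_um
}

#' Measure wound widths over a rendered time series
#' @param series list of binary masks as returned by [render_wound_series()].
#' @return data.frame with `t_min` and `width_um`.
#' @export
measure_wound_widths <- function(series) {
  data.frame(
    t_min = vapply(series, function(im) attr(im, "t_min"), numeric(1)),
    width_um = vapply(series, wound_width, numeric(1))
  )
}
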