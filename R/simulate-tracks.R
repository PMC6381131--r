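#' Configuration for the biased persistent random-walk simulator
#'
#' Parameters of the generative model behind all synthetic trajectories: a
#' biased, persistent random walk on a 10-minute frame grid. At each step a
#' heading is drawn from a von Mises distribution whose mean is the
#' direction of the vector mixture
#' `persistence_weight * previous_heading + (1 - persistence_weight) * migration_direction`
#' and whose concentration is `bias_kappa`; the step length is the frame
#' interval times a per-step speed drawn from a normal distribution
#' truncated at zero.
#'
#' @param seed integer RNG seed (mandatory; generators never touch global
#'   RNG state outside their own scope).
#' @param n_cells number of cells to simulate.
#' @param n_frames frames per track (default 91, i.e. 15 h at 10-min
#'   frames).
#' @param frame_interval_min minutes between frames (default 10).
#' @param speed_mean_um_min,speed_sd_um_min per-step speed distribution,
#'   um/min. Defaults 0.5 and 0.15, typical of endothelial monolayer
#'   migration.
#' @param bias_kappa von Mises concentration (>= 0) of the heading
#'   distribution; 0 = isotropic, values >= 1e6 are treated as the
#'   ballistic limit (every heading exactly at the mean direction).
#' @param persistence_weight fraction in [0, 1] mixing the previous heading
#'   into the new mean heading.
#' @param arena_um width x height of the field in um. Cells are seeded
#'   uniformly in the arena and are not reflected at its boundary (tracks
#'   may leave the field; statistics are unaffected).
#' @return object of class `"simulation_config"`.
#' @export
simulation_config <- function(seed, n_cells, n_frames = 91,
                              frame_interval_min = 10,
                              speed_mean_um_min = 0.5,
                              speed_sd_um_min = 0.15,
                              bias_kappa = 0, persistence_weight = 0,
                              arena_um = c(1784.22, 1000)) {
  stop_if_not_finite(c(seed, n_cells, n_frames, frame_interval_min,
                       speed_mean_um_min, speed_sd_um_min, bias_kappa,
                       persistence_weight, arena_um), "simulation_config")
  if (n_cells < 1) stop("'n_cells' must be >= 1", call. = FALSE)
  if (n_frames < 2) stop("'n_frames' must be >= 2", call. = FALSE)
  if (frame_interval_min <= 0) stop("'frame_interval_min' must be > 0", call. = FALSE)
  if (speed_mean_um_min < 0) stop("'speed_mean_um_min' must be >= 0", call. = FALSE)
  if (speed_sd_um_min < 0) stop("'speed_sd_um_min' must be >= 0", call. = FALSE)
  if (bias_kappa < 0) stop("'bias_kappa' must be >= 0", call. = FALSE)
  if (persistence_weight < 0 || persistence_weight > 1)
    stop("'persistence_weight' must be in [0, 1]", call. = FALSE)
  if (length(arena_um) != 2 || any(arena_um <= 0))
    stop("'arena_um' must be two positive extents", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_cells = as.integer(n_cells),
         n_frames = as.integer(n_frames),
         frame_interval_min = frame_interval_min,
         speed_mean_um_min = speed_mean_um_min,
         speed_sd_um_min = speed_sd_um_min,
         bias_kappa = bias_kappa, persistence_weight = persistence_weight,
         arena_um = arena_um),
    class = "simulation_config"
  )
}

# kappa at and above which headings collapse onto the mean direction
.BALLISTIC_KAPPA <- 1e6

#' Sample from a von Mises distribution
#'
#' Best–Fisher rejection sampler. `kappa = 0` gives the uniform circular
#' distribution; `kappa >= 1e6` returns the mean direction exactly (the
#' ballistic limit).
#'
#' @param n number of draws.
#' @param mu_deg mean direction, degrees.
#' @param kappa concentration parameter, >= 0.
#' @return angles in degrees in [0, 360).
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 0 || !is.finite(kappa)) stop("'kappa' must be finite and >= 0", call. = FALSE)
  if (n == 0) return(numeric(0))
  if (kappa >= .BALLISTIC_KAPPA) return(rep(wrap_angle(mu_deg), n))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
        theta <- mu + sign(u[3] - 0.5) * acos(f)
        out[i] <- theta
        break
      }
    }
  }
  wrap_angle(rad2deg(out))
}

#' Simulate biased persistent random-walk trajectories
#'
#' Generates `n_cells` tracks of `n_frames` positions on the configured
#' frame grid, with headings drawn per step from a von Mises distribution
#' centred on the mixture of the previous heading (weight
#' `persistence_weight`) and the wound's migration direction (weight
#' `1 - persistence_weight`). Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @param wound a [wound_geometry()] providing the migration direction.
#' @return list with `tracks` (list of [trajectory()]) and `ground_truth`
#'   (list with the true tracks and the generating parameters).
#' @examples
#' cfg <- simulation_config(seed = 1, n_cells = 3, n_frames = 10,
#'                          bias_kappa = 4)
#' sim <- simulate_tracks(cfg, wound_geometry(0))
#' length(sim$tracks)
#' @export
simulate_tracks <- function(config, wound) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(wound, "wound_geometry"))
  mig_angle <- wound$migration_angle_deg
  withr::with_seed(config$seed, {
    tracks <- vector("list", config$n_cells)
    t_min <- (seq_len(config$n_frames) - 1) * config$frame_interval_min
    for (i in seq_len(config$n_cells)) {
      pos <- matrix(0, nrow = config$n_frames, ncol = 2)
      pos[1, ] <- stats::runif(2) * config$arena_um
      heading <- mig_angle  # first step has no history
      for (k in 2:config$n_frames) {
        w <- config$persistence_weight
        mix <- w * angle_to_unit(heading) +
          (1 - w) * wound$migration_direction
        center <- if (sqrt(sum(mix^2)) < 1e-12) mig_angle else unit_to_angle(mix)
        heading <- rvonmises(1, center, config$bias_kappa)
        speed <- max(0, stats::rnorm(1, config$speed_mean_um_min,
                                     config$speed_sd_um_min))
        step <- speed * config$frame_interval_min
        pos[k, ] <- pos[k - 1, ] + step * angle_to_unit(heading)
      }
      tracks[[i]] <- trajectory(i, t_min, pos[, 1], pos[, 2])
    }
    list(tracks = tracks,
         ground_truth = list(true_tracks = tracks, config = config,
                             migration_angle_deg = mig_angle))
  })
}
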