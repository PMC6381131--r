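#' End-to-end synthetic demonstration run
#'
#' Exercises every stage of the pipeline on synthetic data with known
#' ground truth: simulates a directed ("control-like") and an isotropic
#' ("knockout-like") cell population and computes their migration
#' summaries and sector fractions; renders a closing wound series and
#' recovers its closure rate; renders a vessel network and recovers its
#' branch-point count and vascular density; renders a polarity image and
#' recovers organelle angles; and runs the DEG overlap logic on a
#' constructed table pair. Each recovered value is compared with its
#' generator ground truth and the report records pass/fail at the stated
#' tolerance. The two motility presets are illustrative parameter choices,
#' not fits to any measured genotype.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir optional directory; when given, the report (markdown),
#'   per-cell CSVs and a polar-plot PNG are written there alongside the
#'   resolved configuration (JSON).
#' @param n_cells cells per population (default 200).
#' @return list of class `"sproutpol_demo"` with elements `checks`
#'   (data.frame: check, value, truth, tolerance, pass), `control`,
#'   `knockout`, `wound`, `vessels`, `deg`, `config`.
#' @export
run_demo <- function(seed = 1, out_dir = NULL, n_cells = 200) {
  wound <- wound_geometry(0)
  checks <- list()
  add <- function(name, value, truth, tol) {
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, value = value, truth = truth, tolerance = tol,
      pass = abs(value - truth) <= tol)
  }

  # -- directed vs isotropic migration ---------------------------------
  cfg_ctl <- simulation_config(seed = seed, n_cells = n_cells,
                               bias_kappa = 8, persistence_weight = 0.3)
  cfg_ko <- simulation_config(seed = seed + 1, n_cells = n_cells,
                              bias_kappa = 0, persistence_weight = 0)
  ctl <- simulate_tracks(cfg_ctl, wound)
  ko <- simulate_tracks(cfg_ko, wound)
  sum_ctl <- lapply(ctl$tracks, summarize_track, wound = wound)
  sum_ko <- lapply(ko$tracks, summarize_track, wound = wound)
  pop_ctl <- population_summary(sum_ctl, wound)
  pop_ko <- population_summary(sum_ko, wound)
  se <- sqrt((1 / 3) * (2 / 3) / n_cells)
  add("isotropic_sector_fraction", pop_ko$sector_fraction, 1 / 3, 4 * se)
  add("isotropic_mean_persistence",
      mean(vapply(sum_ko, function(s) s$persistence, numeric(1))),
      sqrt(pi) / (2 * sqrt(cfg_ko$n_frames - 1)), 0.05)

  # -- wound closure recovery ------------------------------------------
  cfg_w <- simulation_config(seed = seed, n_cells = 1)
  series <- render_wound_series(900, 1, cfg_w)
  widths <- measure_wound_widths(series)
  wc <- wound_closure(widths$t_min, widths$width_um)
  add("wound_closure_rate_um_min", wc$closure_rate_um_min, 1, 0.05)

  # -- vessel morphometry recovery -------------------------------------
  net <- render_vessel_network(12, 0.04, seed = seed)
  bp <- branch_points(net$image,
                      merge_radius_um = 2 * net$ground_truth$stroke_width_um)
  add("branch_point_count", bp$count, 12, 0)
  add("vascular_density_pct", vascular_density(net$image),
      100 * net$ground_truth$true_density, 1e-6)

  # -- polarity recovery ------------------------------------------------
  true_angles <- c(0, 37, 90, 180, 270)
  nuclei <- lapply(seq_along(true_angles), function(i) {
    nucleus_shape(c(25 + 40 * (i - 1), 30), 16, 8, orientation_deg = 0)
  })
  pol_img <- render_polarity_image(nuclei, true_angles, 12,
                                   image_shape_px = c(120, 400),
                                   pixel_size_um = 0.5, seed = seed)
  pol <- measure_polarity_image(pol_img)
  pol <- pol[order(pol$x_um), ]
  add("polarity_angle_max_error_deg",
      max(angle_distance(pol$organelle_angle_deg, true_angles)), 0, 5)

  # -- DEG overlap -------------------------------------------------------
  deg <- simulate_deg_tables(500, 20, 15, seed = seed)
  ov <- deg_overlap(deg$a, deg$b)
  add("deg_common", ov$n_common, 20, 0)
  add("deg_concordant", ov$n_concordant, 15, 0)

  checks <- do.call(rbind, checks)
  res <- structure(
    list(checks = checks,
         control = pop_ctl, knockout = pop_ko, wound = wc,
         vessels = list(branch_points = bp$count,
                        density_pct = vascular_density(net$image)),
         deg = ov,
         config = list(seed = seed, n_cells = n_cells,
                       control = unclass(cfg_ctl), knockout = unclass(cfg_ko))),
    class = "sproutpol_demo")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res$config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(checks, file.path(out_dir, "checks.csv"),
                     row.names = FALSE)
    utils::write.csv(migration_summary_df(sum_ctl),
                     file.path(out_dir, "control_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(migration_summary_df(sum_ko),
                     file.path(out_dir, "knockout_cells.csv"),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, "polar_displacement.png"),
                   width = 900, height = 480)
    graphics::par(mfrow = c(1, 2))
    plot_polar_angles(pop_ctl$displacement_angles_deg,
                      main = "control-like displacement angles")
    plot_polar_angles(pop_ko$displacement_angles_deg,
                      main = "knockout-like displacement angles")
    grDevices::dev.off()
    writeLines(format_demo_report(res), file.path(out_dir, "report.md"))
  }
  res
}

# flatten a list of migration summaries to a per-cell table
migration_summary_df <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(track_id = s$track_id,
               total_path_um = s$total_path_um,
               net_displacement_um = s$net_displacement_um,
               average_speed_um_min = s$average_speed_um_min,
               persistence = s$persistence,
               displacement_angle_deg = s$displacement_angle_deg)
  }))
}

#' Polar scatter of angles
#'
#' Base-graphics rose-style plot: unit-radius points at each angle,
#' 0 degrees (the migration direction) to the right, counter-clockwise,
#' with the conventional 120-degree scoring sector drawn in bold.
#'
#' @param angles_deg angles in degrees (NA dropped).
#' @param sector_center_deg,sector_width_deg scoring sector (default the
#'   120-degree window at 0).
#' @param main plot title.
#' @return invisibly, the sector fraction.
#' @export
plot_polar_angles <- function(angles_deg, sector_center_deg = 0,
                              sector_width_deg = 120, main = "") {
  a <- angles_deg[!is.na(angles_deg)]
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey60")
  sec <- deg2rad(seq(sector_center_deg - sector_width_deg / 2,
                     sector_center_deg + sector_width_deg / 2,
                     length.out = 60))
  graphics::lines(1.08 * cos(sec), 1.08 * sin(sec), lwd = 3)
  r <- deg2rad(a)
  graphics::points(cos(r), sin(r), pch = 16,
                   col = grDevices::adjustcolor("steelblue", 0.6))
  sf <- as.numeric(sector_fraction(a, sector_center_deg, sector_width_deg))
  graphics::text(0, -1.2, sprintf("sector fraction = %.2f", sf), cex = 0.9)
  invisible(sf)
}

format_demo_report <- function(res) {
  ck <- res$checks
  c("# sproutpol synthetic demonstration",
    "",
    sprintf("Seed %d; %d cells per population.", res$config$seed,
            res$config$n_cells),
    "",
    "| check | value | ground truth | tol | pass |",
    "|---|---|---|---|---|",
    sprintf("| %s | %.4g | %.4g | %.3g | %s |", ck$check, ck$value,
            ck$truth, ck$tolerance, ifelse(ck$pass, "yes", "NO")),
    "",
    sprintf("Control-like sector fraction: %.3f; knockout-like: %.3f.",
            res$control$sector_fraction, res$knockout$sector_fraction),
    sprintf("DEG overlap: %d common, %d concordant, %d discordant.",
            res$deg$n_common, res$deg$n_concordant, res$deg$n_discordant))
}

#' @export
print.sproutpol_demo <- function(x, ...) {
  cat(format_demo_report(x), sep = "\n")
  invisible(x)
}
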