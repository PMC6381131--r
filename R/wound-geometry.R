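#' Scratch-wound reference frame
#'
#' Defines the migration reference frame of a scratch-wound assay: the
#' scratch axis (the direction along the wound) and the migration direction
#' (perpendicular to the scratch, pointing into the gap). All displacement
#' and polarization angles are reported counter-clockwise with the migration
#' direction at 0 degrees, matching the polar-plot convention in which the
#' scored 120-degree sector is centred on the vector perpendicular to the
#' scratch.
#'
#' @param migration_angle_deg direction of migration into the gap, degrees
#'   counter-clockwise from +x in the mathematical (y-up) convention.
#'   Default 0: a vertical scratch with cells migrating rightward.
#' @param initial_margins optional numeric length-2: signed positions of the
#'   two wound margins along the migration direction, um (lower, upper).
#' @return object of class `"wound_geometry"` with unit vectors
#'   `migration_direction` and `scratch_axis`.
#' @export
wound_geometry <- function(migration_angle_deg = 0, initial_margins = NULL) {
  stop_if_not_finite(migration_angle_deg, "migration_angle_deg")
  if (!is.null(initial_margins)) {
    stop_if_not_finite(initial_margins, "initial_margins")
    if (length(initial_margins) != 2)
      stop("'initial_margins' must have length 2", call. = FALSE)
    initial_margins <- sort(initial_margins)
  }
  mig <- angle_to_unit(migration_angle_deg)
  structure(
    list(migration_angle_deg = wrap_angle(migration_angle_deg),
         migration_direction = mig,
         scratch_axis = angle_to_unit(migration_angle_deg + 90),
         initial_margins = initial_margins),
    class = "wound_geometry"
  )
}

#' @export
print.wound_geometry <- function(x, ...) {
  cat(sprintf("wound_geometry: migration direction %.1f deg (ccw from +x, y up)\n",
              x$migration_angle_deg))
  if (!is.null(x$initial_margins))
    cat(sprintf("  initial margins at %.1f / %.1f um along migration axis\n",
                x$initial_margins[1], x$initial_margins[2]))
  invisible(x)
}
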