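#' Angle utilities
#'
#' Small helpers for circular (mod 360) and axial (mod 180) angles, all in
#' degrees. Directional angles follow the mathematical convention:
#' counter-clockwise, 0 along +x, y pointing up. Image-space measurements
#' (y pointing down) are flipped before any angle is computed.
#'
#' @name angles
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap a directional angle into [0, 360)
#' @param x angle(s) in degrees.
#' @return angle(s) in [0, 360).
#' @export
wrap_angle <- function(x) ((x %% 360) + 360) %% 360

#' Wrap an axial angle (an orientation without direction) into [0, 180)
#' @param x angle(s) in degrees.
#' @return angle(s) in [0, 180).
#' @export
wrap_axial <- function(x) ((x %% 180) + 180) %% 180

#' Smallest circular distance between two directional angles
#' @param a,b angles in degrees.
#' @return distance in [0, 180].
#' @export
angle_distance <- function(a, b) {
  d <- abs(wrap_angle(a) - wrap_angle(b))
  pmin(d, 360 - d)
}

#' Smallest distance between two axial angles
#' @param a,b axial angles in degrees (interpreted mod 180).
#' @return distance in [0, 90].
#' @export
axial_distance <- function(a, b) {
  d <- abs(wrap_axial(a) - wrap_axial(b))
  pmin(d, 180 - d)
}

# unit vector of a directional angle (math convention)
angle_to_unit <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  c(cos(t), sin(t))
}

# directional angle of a vector (math convention), degrees in [0, 360)
unit_to_angle <- function(v) {
  wrap_angle(rad2deg(atan2(v[2], v[1])))
}

stop_if_not_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' must be finite, got: %s", name,
                 paste(utils::head(x, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}
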