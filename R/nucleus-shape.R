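#' Nuclear shape descriptor
#'
#' A fitted (or ground-truth) 2-D nucleus: centroid, long-axis caliper
#' length ("Height"), maximum perpendicular extent ("Width") and axial
#' orientation. Ellipticity is Height / Width and is always >= 1.
#'
#' @param centroid_um numeric length-2, (x, y) in um.
#' @param height_um long-axis caliper extent, um.
#' @param width_um maximum extent perpendicular to the long axis, um; must
#'   satisfy `0 < width_um <= height_um`.
#' @param orientation_deg axial orientation of the long axis in [0, 180)
#'   (mathematical convention, y up).
#' @return object of class `"nucleus_shape"`; `$ellipticity` is
#'   height / width.
#' @export
nucleus_shape <- function(centroid_um, height_um, width_um, orientation_deg) {
  stop_if_not_finite(c(centroid_um, height_um, width_um, orientation_deg),
                     "nucleus_shape")
  if (length(centroid_um) != 2)
    stop("'centroid_um' must be length 2", call. = FALSE)
  if (width_um <= 0) stop("'width_um' must be > 0", call. = FALSE)
  if (height_um < width_um)
    stop("'height_um' must be >= 'width_um' (long axis first)", call. = FALSE)
  structure(
    list(centroid_um = as.numeric(centroid_um), height_um = height_um,
         width_um = width_um, orientation_deg = wrap_axial(orientation_deg),
         ellipticity = height_um / width_um),
    class = "nucleus_shape"
  )
}

#' @export
print.nucleus_shape <- function(x, ...) {
  cat(sprintf(
    "nucleus_shape: centroid (%.1f, %.1f) um, H %.2f x W %.2f um (ellipticity %.2f), %.1f deg\n",
    x$centroid_um[1], x$centroid_um[2], x$height_um, x$width_um,
    x$ellipticity, x$orientation_deg))
  invisible(x)
}
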