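#' Pixel size from field width
#'
#' Converts an imaging field width in micrometres and an image width in
#' pixels into the physical pixel size. The standard scratch-assay field of
#' 1784.22 um imaged at 1920 px gives 0.93 um/pixel (2-decimal report); the
#' unrounded value is used internally for all conversions.
#'
#' @param field_width_um physical width of the imaged field, in micrometres.
#' @param image_width_px width of the image, in pixels.
#' @return pixel size in um/pixel (unrounded). Use [format_pixel_size()] for
#'   the conventional 2-decimal report.
#' @examples
#' pixel_size(1784.22, 1920)          # 0.9292813
#' format_pixel_size(pixel_size(1784.22, 1920))  # "0.93"
#' @export
pixel_size <- function(field_width_um, image_width_px) {
  stop_if_not_finite(field_width_um, "field_width_um")
  stop_if_not_finite(image_width_px, "image_width_px")
  if (field_width_um <= 0) stop("'field_width_um' must be > 0", call. = FALSE)
  if (image_width_px <= 0) stop("'image_width_px' must be > 0", call. = FALSE)
  field_width_um / image_width_px
}

#' @rdname pixel_size
#' @param pixel_size_um pixel size in um/pixel.
#' @export
format_pixel_size <- function(pixel_size_um) {
  formatC(round(pixel_size_um, 2), format = "f", digits = 2)
}

#' Image calibration
#'
#' Bundles the field-of-view geometry with the derived pixel size.
#'
#' @inheritParams pixel_size
#' @return an object of class `"calibration"` with fields `field_width_um`,
#'   `image_width_px`, `pixel_size_um`.
#' @export
calibration <- function(field_width_um, image_width_px) {
  ps <- pixel_size(field_width_um, image_width_px)
  structure(
    list(field_width_um = field_width_um,
         image_width_px = image_width_px,
         pixel_size_um = ps),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration: %.2f um / %d px = %s um/pixel\n",
              x$field_width_um, as.integer(x$image_width_px),
              format_pixel_size(x$pixel_size_um)))
  invisible(x)
}
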