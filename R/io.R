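#' Write / read a calibrated image as TIFF plus sidecar JSON
#'
#' Images are stored as single- or multi-page TIFF (one channel per page)
#' with the physical pixel size recorded in a sidecar JSON file
#' (`<path>.json`, `{"pixel_size_um": ...}`) so calibration survives the
#' round trip.
#'
#' @param image a [label_image()].
#' @param path output TIFF path.
#' @return `read_image_tiff` returns a [label_image()].
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "label_image"))
  px <- image$pixels
  pages <- if (is.matrix(px)) list(px) else
    lapply(seq_len(dim(px)[3]), function(k) px[, , k])
  # tiff stores [0,1] floats; rescale intensities if needed
  rng <- range(unlist(lapply(pages, range)))
  scale <- if (rng[2] > 1 || rng[1] < 0) {
    span <- max(rng[2] - rng[1], 1e-12)
    pages <- lapply(pages, function(p) (p - rng[1]) / span)
    c(offset = rng[1], span = span)
  } else c(offset = 0, span = 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size_um,
         channels = image$channels,
         intensity_offset = unname(scale["offset"]),
         intensity_span = unname(scale["span"])),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    p * meta$intensity_span + meta$intensity_offset
  })
  px <- if (length(pages) == 1) pages[[1]] else
    array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  channels <- meta$channels
  if (!is.null(channels) && length(channels) == 0) channels <- NULL
  label_image(px, meta$pixel_size_um, channels = channels)
}

#' Write ground truth as JSON
#' @param ground_truth list of ground-truth quantities.
#' @param path output path.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
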