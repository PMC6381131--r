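#' Calibrated label image
#'
#' A thin container for 2-D image data with physical calibration. Pixels are
#' stored as a matrix (single channel) or a 3-D array (row, col, channel)
#' with named channels. The coordinate convention is 0-based pixel indices
#' with pixel-centre origin: pixel `[r, c]` (1-based R indices) has centre
#' `x = (c - 1) * pixel_size`, `y = (r - 1) * pixel_size`, x rightward and y
#' downward in image space. Angle-valued measurements flip to the y-upward
#' mathematical convention before computing angles.
#'
#' @param pixels numeric matrix or 3-D array (row, col, channel).
#' @param pixel_size_um physical pixel size, um/pixel; must be > 0.
#' @param channels optional character vector of channel names.
#' @return object of class `"label_image"`.
#' @export
label_image <- function(pixels, pixel_size_um, channels = NULL) {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3)))
    stop("'pixels' must be a matrix or a 3-D array", call. = FALSE)
  stop_if_not_finite(pixel_size_um, "pixel_size_um")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be > 0", call. = FALSE)
  if (!is.null(channels)) {
    nch <- if (is.matrix(pixels)) 1L else dim(pixels)[3]
    if (length(channels) != nch)
      stop("length(channels) must equal the number of channels", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um, channels = channels),
    class = "label_image"
  )
}

#' @export
print.label_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("label_image: %d x %d px", d[1], d[2]))
  if (length(d) == 3) cat(sprintf(" x %d channels", d[3]))
  cat(sprintf(", %.4g um/pixel", x$pixel_size_um))
  if (!is.null(x$channels)) cat(" [", paste(x$channels, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Extract one channel of a label image as a single-channel label image
#' @param image a [label_image()].
#' @param channel channel name or index.
#' @return a single-channel `label_image`.
#' @export
get_channel <- function(image, channel) {
  stopifnot(inherits(image, "label_image"))
  px <- image$pixels
  if (is.matrix(px)) {
    if (!(identical(channel, 1L) || identical(channel, 1) ||
          (is.character(channel) && !is.null(image$channels) &&
           channel == image$channels[1])))
      stop("single-channel image: channel must be 1", call. = FALSE)
    return(image)
  }
  idx <- if (is.character(channel)) {
    if (is.null(image$channels)) stop("image has unnamed channels", call. = FALSE)
    match(channel, image$channels)
  } else as.integer(channel)
  if (is.na(idx) || idx < 1 || idx > dim(px)[3])
    stop(sprintf("channel '%s' not found", channel), call. = FALSE)
  label_image(px[, , idx], image$pixel_size_um,
              channels = if (!is.null(image$channels)) image$channels[idx])
}

# x/y physical coordinate grids for pixel centres (image space, y down)
pixel_centers <- function(n_rows, n_cols, pixel_size_um) {
  list(
    x = matrix((seq_len(n_cols) - 1) * pixel_size_um,
               nrow = n_rows, ncol = n_cols, byrow = TRUE),
    y = matrix((seq_len(n_rows) - 1) * pixel_size_um,
               nrow = n_rows, ncol = n_cols)
  )
}

# 8-connected component labelling: EBImage::bwlabel is 4-connected, so
# merge labels that touch diagonally (union-find over diagonal adjacencies)
label_components8 <- function(m) {
  lab <- EBImage::bwlabel(m)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  for (k in seq_len(nrow(pairs))) {
    ra <- find_root(pairs[k, 1]); rb <- find_root(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find_root, numeric(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

as_binary_matrix <- function(image, arg = "mask") {
  stopifnot(inherits(image, "label_image"))
  px <- image$pixels
  if (!is.matrix(px)) stop(sprintf("'%s' must be single-channel", arg), call. = FALSE)
  if (!all(px %in% c(0, 1))) stop(sprintf("'%s' must be binary (0/1)", arg), call. = FALSE)
  px
}

#' Rectangular region of interest in physical units
#'
#' @param x,y top-left corner in um (image-space coordinates, y down).
#' @param width,height extent in um; must be > 0.
#' @param label optional label.
#' @return object of class `"roi"`.
#' @export
roi_rect <- function(x, y, width, height, label = NULL) {
  stop_if_not_finite(c(x, y, width, height), "roi")
  if (width <= 0 || height <= 0) stop("roi extent must be > 0", call. = FALSE)
  structure(list(x = x, y = y, width = width, height = height, label = label),
            class = "roi")
}

# logical matrix: which pixel centres fall inside the roi; NULL roi = all.
# errors when the roi lies outside the image.
roi_pixel_mask <- function(image, roi) {
  d <- dim(image$pixels)[1:2]
  if (is.null(roi)) return(matrix(TRUE, d[1], d[2]))
  stopifnot(inherits(roi, "roi"))
  ps <- image$pixel_size_um
  ext_x <- d[2] * ps
  ext_y <- d[1] * ps
  if (roi$x < -ps / 2 || roi$y < -ps / 2 ||
      roi$x + roi$width > ext_x + ps / 2 || roi$y + roi$height > ext_y + ps / 2)
    stop("roi lies outside the image", call. = FALSE)
  ctr <- pixel_centers(d[1], d[2], ps)
  ctr$x >= roi$x & ctr$x < roi$x + roi$width &
    ctr$y >= roi$y & ctr$y < roi$y + roi$height
}
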