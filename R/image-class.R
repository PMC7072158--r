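#' Construct a fluorescence image
#'
#' A `cell_image` is a plain numeric matrix of nonnegative intensities
#' (arbitrary fluorescence units, AFU) carrying the physical pixel size in
#' micrometres and optional channel / time-point labels as attributes. All
#' segmentation and quantification functions accept either a `cell_image` or
#' a bare matrix (in which case `pixel_size` must be supplied where needed).
#'
#' @param pixels numeric matrix of intensities, at least 8 x 8, all values
#'   finite and >= 0.
#' @param pixel_size physical size of one pixel in micrometres (> 0).
#' @param channel optional channel label (e.g. `"mCherry"`).
#' @param time_index optional integer frame index within a time series.
#'
#' @return a `cell_image` object (numeric matrix with attributes
#'   `pixel_size`, `channel`, `time_index`).
#' @examples
#' img <- cell_image(matrix(runif(64 * 64), 64), pixel_size = 0.1)
#' pixel_size(img)
#' @export
cell_image <- function(pixels, pixel_size, channel = NULL, time_index = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    abort("images must be at least 8 x 8 pixels.")
  }
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("pixel intensities must be finite and nonnegative.")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (um/pixel).")
  }
  structure(pixels,
    pixel_size = as.numeric(pixel_size),
    channel = channel,
    time_index = time_index,
    class = c("cell_image", class(pixels))
  )
}

#' @rdname cell_image
#' @param x a `cell_image`.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size")
  if (is.null(ps)) abort("object carries no `pixel_size` attribute.")
  ps
}

#' @export
print.cell_image <- function(x, ...) {
  cat(sprintf(
    "<cell_image> %d x %d px, %.3g um/px, range [%.3g, %.3g]\n",
    nrow(x), ncol(x), pixel_size(x), min(x), max(x)
  ))
  invisible(x)
}

# Coerce an image-or-matrix argument to a numeric matrix, keeping validation
# in one place.
as_pixel_matrix <- function(image) {
  if (inherits(image, "cell_image")) {
    return(unclass_image(image))
  }
  if (is.matrix(image) && is.numeric(image)) {
    return(image)
  }
  abort("`image` must be a `cell_image` or a numeric matrix.")
}

unclass_image <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Bundle the three masks of the annulus procedure
#'
#' @param cell logical matrix: the filled cell footprint.
#' @param pm_annulus logical matrix: the plasma-membrane rim (cell minus
#'   eroded interior).
#' @param interior logical matrix: the eroded interior (cytoplasm region).
#' @param n_erosions_used number of erosions that produced `interior`.
#'
#' @details The three masks satisfy a partition identity: `pm_annulus` and
#'   `interior` are disjoint and their union is `cell`. The constructor
#'   enforces this.
#' @return a `cell_masks` object (list of the three logical matrices plus
#'   `n_erosions_used`).
#' @export
cell_masks <- function(cell, pm_annulus, interior, n_erosions_used) {
  for (m in list(cell, pm_annulus, interior)) {
    if (!is.matrix(m) || !is.logical(m)) abort("masks must be logical matrices.")
    if (!identical(dim(m), dim(cell))) abort("mask dimensions must agree.")
  }
  if (any(pm_annulus & interior)) {
    abort("`pm_annulus` and `interior` overlap; masks must partition the cell.")
  }
  if (!identical(pm_annulus | interior, cell)) {
    abort("`pm_annulus` and `interior` must tile `cell` exactly.")
  }
  structure(
    list(
      cell = cell, pm_annulus = pm_annulus, interior = interior,
      n_erosions_used = as.integer(n_erosions_used)
    ),
    class = "cell_masks"
  )
}

#' @export
print.cell_masks <- function(x, ...) {
  cat(sprintf(
    "<cell_masks> cell %d px = annulus %d px + interior %d px (%d erosions)\n",
    sum(x$cell), sum(x$pm_annulus), sum(x$interior), x$n_erosions_used
  ))
  invisible(x)
}
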