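#' Segment the cell footprint from a fluorescence image
#'
#' Thresholds the image (Otsu's method by default, or a fixed intensity),
#' fills internal holes (so nuclei or vacuoles cannot create spurious inner
#' rims), and keeps the largest connected foreground component. This yields
#' the binary cell footprint from which the plasma-membrane annulus is
#' carved.
#'
#' @param image a `cell_image` or numeric matrix.
#' @param method `"otsu"` for automatic thresholding, or a single number
#'   used as a fixed intensity threshold (pixels strictly above it are
#'   foreground).
#' @param min_area minimum component area in pixels; smaller foregrounds
#'   raise a segmentation error.
#' @param fill_holes fill enclosed background holes before component
#'   selection (default `TRUE`).
#'
#' @return a logical matrix, `TRUE` on the selected cell.
#' @seealso [make_pm_annulus()], [erosions_for_physical_width()]
#' @examples
#' cell <- simulate_cell(seed = 1)
#' mask <- segment_cell(cell$image)
#' @export
segment_cell <- function(image, method = "otsu", min_area = 20L,
                         fill_holes = TRUE) {
  px <- as_pixel_matrix(image)
  rng <- range(px)
  if (diff(rng) == 0) {
    abort("segmentation error: image intensity is uniform; no threshold separates foreground from background.")
  }

  if (identical(method, "otsu")) {
    th <- EBImage::otsu(px, range = rng)
  } else if (is.numeric(method) && length(method) == 1L) {
    th <- method
  } else {
    abort("`method` must be \"otsu\" or a single fixed threshold value.")
  }

  bin <- px > th
  if (fill_holes) {
    bin <- EBImage::fillHull(bin) > 0
  }
  lab <- EBImage::bwlabel(bin)
  areas <- tabulate(lab[lab > 0])
  if (length(areas) == 0 || max(areas) < min_area) {
    abort(sprintf(
      "segmentation error: largest foreground component (%d px) is below `min_area` = %d px.",
      if (length(areas)) max(areas) else 0L, as.integer(min_area)
    ))
  }
  lab == which.max(areas)
}

#' Carve the plasma-membrane annulus from a cell mask
#'
#' Implements the annulus procedure used for membrane-to-cytosol
#' quantification: the binary cell mask is eroded `n_erosions` times (one
#' pixel of rim removed per erosion), and the eroded image is subtracted
#' from the original to leave an annulus around the cell periphery
#' corresponding to plasma-membrane fluorescence. The eroded interior
#' defines the cytoplasm region.
#'
#' The structuring element controls the rim geometry. Iterating the 3 x 3
#' square (8-connected, ImageJ binary-erode semantics) measures depth in
#' the Chebyshev metric, so on round cells the rim comes out sqrt(2) times
#' wider along diagonals and the annulus mean picks up cytosolic signal;
#' the diamond (4-connected) element has the opposite, axial bias. The
#' default `"octagon"` alternates the two, which approximates an isotropic
#' Euclidean rim (worst-case width error ~6% instead of ~41%) and
#' materially reduces the bias of `%PM` on convex cells. Use `"square"` to
#' reproduce ImageJ's behaviour exactly.
#'
#' @param cell logical matrix from [segment_cell()]; must be a single
#'   connected component.
#' @param n_erosions number of erosions (>= 1); see
#'   [erosions_for_physical_width()] to pick this from the pixel size.
#' @param element structuring element: `"octagon"` (default, alternating
#'   square/diamond), `"square"` (3 x 3, 8-connected) or `"diamond"`
#'   (4-connected plus shape).
#'
#' @return a [cell_masks()] object: `cell`, `pm_annulus`, `interior`,
#'   `n_erosions_used`. Annulus and interior always partition the cell.
#' @examples
#' sq <- matrix(FALSE, 16, 16)
#' sq[4:13, 4:13] <- TRUE
#' masks <- make_pm_annulus(sq, n_erosions = 2)
#' sum(masks$interior) # 36: the centred 6 x 6 survives two erosions
#' @export
make_pm_annulus <- function(cell, n_erosions = 2L,
                            element = c("octagon", "square", "diamond")) {
  element <- match.arg(element)
  if (!is.matrix(cell) || !is.logical(cell)) {
    abort("`cell` must be a logical matrix.")
  }
  if (!any(cell)) abort("`cell` mask is empty.")
  n_comp <- max(EBImage::bwlabel(cell))
  if (n_comp != 1L) {
    abort(sprintf(
      "`cell` must be a single connected component (found %d).", n_comp
    ))
  }
  if (n_erosions < 1L) abort("`n_erosions` must be >= 1.")

  square <- EBImage::makeBrush(3, shape = "box")
  diamond <- matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)
  interior <- cell
  for (i in seq_len(n_erosions)) {
    kern <- switch(element,
      square = square,
      diamond = diamond,
      octagon = if (i %% 2 == 1) square else diamond
    )
    interior <- EBImage::erode(interior, kern) > 0.5
  }
  if (!any(interior)) {
    abort(sprintf(
      "annulus-degenerate: %d erosions empty the mask; the object is too small for the requested rim.",
      as.integer(n_erosions)
    ))
  }
  cell_masks(cell, cell & !interior, interior,
    n_erosions_used = n_erosions
  )
}

#' Number of erosions matching a physical rim width
#'
#' The rim carved by [make_pm_annulus()] is `n_erosions` pixels wide, so the
#' erosion count that approximates a fixed physical membrane-rim width
#' (~400 nm) depends on the zoom: `round(target_width / pixel_size)`,
#' clipped to the 2-4 range used in practice.
#'
#' @param pixel_size pixel size in um/pixel (> 0).
#' @param target_width desired rim width in um; default 0.4 um.
#'
#' @return integer erosion count in `[2, 4]`.
#' @examples
#' erosions_for_physical_width(0.2) # 2
#' erosions_for_physical_width(0.1) # 4
#' @export
erosions_for_physical_width <- function(pixel_size, target_width = 0.4) {
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  if (target_width <= 0) abort("`target_width` must be > 0.")
  n <- round(target_width / pixel_size)
  as.integer(min(max(n, 2L), 4L))
}
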