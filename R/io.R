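#' Read and write fluorescence images as TIFF
#'
#' Images are stored as 16-bit grayscale TIFF (the common confocal bit
#' depth). On export intensities are quantized to 16 bits over `[0,
#' max_afu]`; on import they are rescaled back to AFU. A JSON sidecar
#' (`<path>.json`) records `pixel_size`, `max_afu` and any extra metadata
#' so the round trip preserves physical units.
#'
#' @param image a `cell_image` (or matrix plus `pixel_size`).
#' @param path output TIFF path.
#' @param max_afu full-scale intensity mapped to 65535; defaults to the
#'   image maximum.
#' @param metadata named list merged into the JSON sidecar (e.g. ground
#'   truth of a synthetic cell).
#' @return `write_image_tiff()` returns `path` invisibly;
#'   `read_image_tiff()` returns a `cell_image`.
#' @export
write_image_tiff <- function(image, path, max_afu = NULL, metadata = list()) {
  px <- as_pixel_matrix(image)
  ps <- if (inherits(image, "cell_image")) pixel_size(image) else {
    abort("`image` must be a `cell_image` so the pixel size can be recorded.")
  }
  max_afu <- max_afu %||% max(px, 1)
  scaled <- pmin(pmax(px / max_afu, 0), 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  sidecar <- c(
    list(pixel_size_um = ps, max_afu = max_afu, bits = 16L),
    metadata
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    abort("missing JSON sidecar; cannot recover pixel size and intensity scale.")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  cell_image(px * meta$max_afu, pixel_size = meta$pixel_size_um)
}

#' Write a binary mask as an 8-bit TIFF
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_tiff <- function(mask, path) {
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix.")
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Tabular readers/writers for binding data
#'
#' Thin wrappers fixing the CSV schemas used throughout: sensorgrams
#' (`time_s`, `response_RU`, `phase`, `conc_M`), isotherms (`conc_M`,
#' `Req_RU`) and gel lanes (`lane`, `supernatant`, `pellet`).
#'
#' @param data tibble in the corresponding schema.
#' @param path CSV path.
#' @name binding_io
#' @return readers return a validated tibble; writers return `path`
#'   invisibly.
NULL

#' @rdname binding_io
#' @export
read_sensorgram_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("time_s", "response_RU", "phase", "conc_M")
  if (!all(need %in% names(df))) {
    abort(sprintf("sensorgram CSV needs columns: %s.", paste(need, collapse = ", ")))
  }
  df
}

#' @rdname binding_io
#' @export
write_sensorgram_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname binding_io
#' @export
read_isotherm_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("conc_M", "Req_RU") %in% names(df))) {
    abort("isotherm CSV needs columns `conc_M`, `Req_RU`.")
  }
  df
}

#' @rdname binding_io
#' @export
read_gel_lanes_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("lane", "supernatant", "pellet") %in% names(df))) {
    abort("gel-lane CSV needs columns `lane`, `supernatant`, `pellet`.")
  }
  df
}
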