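#' Membrane-to-cytosol localization metrics for one image
#'
#' Computes the core image statistics of membrane-recruitment assays:
#' `I_PM`, the mean pixel intensity over the plasma-membrane annulus;
#' `I_Cyt`, the mean cytoplasmic intensity; the PM index `I_PM / I_Cyt`;
#' and percent plasma-membrane localization,
#' `%PM = 100 * I_PM / (I_PM + I_Cyt)`.
#'
#' Both ratio metrics are invariant under multiplying the whole image by a
#' positive gain. They are *not* invariant under an additive offset: a
#' constant background added to every pixel pulls `%PM` toward 50 (and the
#' PM index toward 1), which is why `background_subtract` is offered. It is
#' off by default: the classical protocol computes the ratios on raw
#' intensities.
#'
#' @param image a `cell_image` or numeric matrix.
#' @param masks a [cell_masks()] object for this image (from
#'   [make_pm_annulus()] or the ground truth of [simulate_cell()]).
#' @param cytoplasm `"whole"` (default) averages the entire eroded interior;
#'   `"rois"` reproduces the operator practice of averaging `n_rois` sampled
#'   square regions inside the cytoplasm.
#' @param n_rois,roi_size number and side length (pixels) of sampled
#'   cytoplasmic regions when `cytoplasm = "rois"`.
#' @param background_subtract subtract the mean intensity outside the cell
#'   mask before computing the ratios.
#' @param seed seed for ROI sampling; `NULL` uses the current RNG state.
#'
#' @return a one-row tibble: `i_pm`, `i_cyt`, `pm_index`, `percent_pm`,
#'   `n_pm_px`, `n_cyt_px`, `pm_index_defined`. When `I_Cyt` is zero the PM
#'   index is undefined: `pm_index` is `NA` and `pm_index_defined` is
#'   `FALSE` (with `percent_pm` = 100). If both regions have zero mean
#'   intensity the metrics are undefined and an error is raised.
#' @examples
#' cell <- simulate_cell(poisson_noise = FALSE, gaussian_sd = 0)
#' quantify_localization(cell$image, cell$truth$masks)
#' @export
quantify_localization <- function(image, masks,
                                  cytoplasm = c("whole", "rois"),
                                  n_rois = 2L, roi_size = 5L,
                                  background_subtract = FALSE,
                                  seed = NULL) {
  cytoplasm <- match.arg(cytoplasm)
  px <- as_pixel_matrix(image)
  if (!inherits(masks, "cell_masks")) abort("`masks` must be a `cell_masks` object.")
  if (!identical(dim(px), dim(masks$cell))) {
    abort("`masks` dimensions do not match `image`.")
  }
  if (!any(masks$pm_annulus)) abort("metric error: plasma-membrane annulus is empty.")
  if (!any(masks$interior)) abort("metric error: cytoplasm region is empty.")

  if (isTRUE(background_subtract)) {
    px <- px - mean(px[!masks$cell])
  }

  i_pm <- mean(px[masks$pm_annulus])
  i_cyt <- switch(cytoplasm,
    whole = mean(px[masks$interior]),
    rois = with_optional_seed(seed, roi_mean(px, masks$interior, n_rois, roi_size))
  )

  if (i_pm + i_cyt == 0) {
    abort("undefined-metric error: zero intensity over both membrane and cytoplasm.")
  }
  defined <- i_cyt > 0
  tibble::tibble(
    i_pm = i_pm,
    i_cyt = i_cyt,
    pm_index = if (defined) i_pm / i_cyt else NA_real_,
    percent_pm = 100 * i_pm / (i_pm + i_cyt),
    n_pm_px = sum(masks$pm_annulus),
    n_cyt_px = sum(masks$interior),
    pm_index_defined = defined
  )
}

# Mean of n_rois square ROI means sampled inside the interior mask.
roi_mean <- function(px, interior, n_rois, roi_size) {
  centers <- which(interior, arr.ind = TRUE)
  pick <- centers[sample.int(nrow(centers), n_rois, replace = TRUE), ,
    drop = FALSE
  ]
  half <- floor(roi_size / 2)
  means <- vapply(seq_len(n_rois), function(k) {
    rows <- max(1, pick[k, 1] - half):min(nrow(px), pick[k, 1] + half)
    cols <- max(1, pick[k, 2] - half):min(ncol(px), pick[k, 2] + half)
    sub <- interior[rows, cols, drop = FALSE]
    mean(px[rows, cols, drop = FALSE][sub])
  }, numeric(1))
  mean(means)
}

#' Quantify every frame of a time-lapse stack
#'
#' Runs the localization metrics on each frame of an image stack. By
#' default each frame is re-segmented (cells move little over a few
#' minutes, but focus and intensity drift); frames whose segmentation fails
#' fall back to the first successfully segmented frame's masks.
#'
#' @param stack a `synthetic_timeseries`, or a list of `cell_image` /
#'   matrix frames.
#' @param masks `NULL` (default) to segment each frame with
#'   [segment_cell()] + [make_pm_annulus()]; a single [cell_masks()] to
#'   reuse for all frames; or a list of per-frame `cell_masks`.
#' @param n_erosions erosion count for per-frame segmentation; `NULL`
#'   derives it from the pixel size via [erosions_for_physical_width()].
#' @param method threshold method passed to [segment_cell()].
#' @param ... further arguments passed to [quantify_localization()].
#'
#' @return a tibble with one row per frame (`frame`, then the
#'   [quantify_localization()] columns).
#' @export
quantify_stack <- function(stack, masks = NULL, n_erosions = NULL,
                           method = "otsu", ...) {
  frames <- stack_frames(stack)
  n <- length(frames)

  per_frame_masks <- vector("list", n)
  if (inherits(masks, "cell_masks")) {
    per_frame_masks[] <- list(masks)
  } else if (is.list(masks) && !is.null(masks)) {
    if (length(masks) != n) abort("`masks` list must have one entry per frame.")
    per_frame_masks <- masks
  } else {
    fallback <- NULL
    for (k in seq_len(n)) {
      mk <- tryCatch(
        {
          ne <- n_erosions %||%
            erosions_for_physical_width(pixel_size(frames[[k]]))
          make_pm_annulus(segment_cell(frames[[k]], method = method), ne)
        },
        error = function(e) NULL
      )
      if (is.null(mk)) {
        if (is.null(fallback)) {
          abort("segmentation failed on the first frame; cannot establish fallback masks.")
        }
        warn(sprintf("frame %d: segmentation failed; reusing earlier masks.", k))
        mk <- fallback
      } else {
        fallback <- mk
      }
      per_frame_masks[[k]] <- mk
    }
  }

  purrr::map2_dfr(seq_len(n), per_frame_masks, function(k, mk) {
    dplyr::bind_cols(
      tibble::tibble(frame = k),
      quantify_localization(frames[[k]], mk, ...)
    )
  })
}

#' Dissociation index of a recruitment / depletion time series
#'
#' The dissociation index is the ratio of the PM index (`I_PM / I_Cyt`)
#' before treatment to the PM index after treatment (typically the baseline
#' frame and the frame 5 min post-rapamycin). Values above 1 indicate loss
#' of membrane localization; a probe that stays put scores 1.
#'
#' @inheritParams quantify_stack
#' @param t_before,t_after frame indices of the before and after time
#'   points; `t_after = NULL` uses the last frame.
#' @param orientation `"before_after"` (default, the reported convention:
#'   dissociation reads > 1) or `"after_before"`.
#'
#' @return a one-row tibble: `pm_index_before`, `pm_index_after`,
#'   `dissociation_index`.
#' @examples
#' ts <- simulate_timeseries(n_frames = 5, pm_decay_rate = 0, seed = 2)
#' dissociation_index(ts, masks = ts$truth$masks)
#' @export
dissociation_index <- function(stack, t_before = 1L, t_after = NULL,
                               masks = NULL, n_erosions = NULL,
                               method = "otsu",
                               orientation = c("before_after", "after_before"),
                               ...) {
  orientation <- match.arg(orientation)
  frames <- stack_frames(stack)
  t_after <- t_after %||% length(frames)
  if (t_before < 1L || t_after > length(frames) || t_before >= t_after) {
    abort("`t_before` and `t_after` must index distinct, ordered frames.")
  }

  q <- quantify_stack(stack, masks = masks, n_erosions = n_erosions,
    method = method, ...
  )
  before <- q$pm_index[q$frame == t_before]
  after <- q$pm_index[q$frame == t_after]
  if (is.na(before) || is.na(after)) {
    abort("PM index undefined at one of the requested time points.")
  }
  di <- if (orientation == "before_after") before / after else after / before
  tibble::tibble(
    pm_index_before = before,
    pm_index_after = after,
    dissociation_index = di
  )
}

stack_frames <- function(stack) {
  if (inherits(stack, "synthetic_timeseries")) {
    return(stack$frames)
  }
  if (is.list(stack) && length(stack) >= 2L) {
    return(stack)
  }
  abort("`stack` must be a `synthetic_timeseries` or a list of >= 2 frames.")
}

#' Normalize measurements to a reference group
#'
#' Rescales values so the reference group (typically wild type) averages
#' 100, the convention used when reporting %PM localization of mutants
#' relative to WT.
#'
#' @param values numeric vector to rescale.
#' @param reference_values numeric vector of reference-group measurements;
#'   their mean must be positive.
#'
#' @return `values * 100 / mean(reference_values)`.
#' @examples
#' normalize_to_reference(35, c(60, 80, 70)) # 50
#' @export
normalize_to_reference <- function(values, reference_values) {
  m <- mean(reference_values)
  if (!is.finite(m) || m <= 0) {
    abort("reference mean must be positive.")
  }
  values * 100 / m
}
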