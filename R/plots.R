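#' Display an image with its annulus and interior outlines
#'
#' Quick visual check of the segmentation: the image as a grayscale
#' raster with the plasma-membrane annulus and interior masks overlaid in
#' translucent colour.
#'
#' @param image a `cell_image` or matrix.
#' @param masks a [cell_masks()] object (optional).
#' @return a ggplot object.
#' @export
plot_cell_masks <- function(image, masks = NULL) {
  px <- as_pixel_matrix(image)
  df <- tibble::tibble(
    row = rep(seq_len(nrow(px)), ncol(px)),
    col = rep(seq_len(ncol(px)), each = nrow(px)),
    intensity = as.vector(px)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "AFU")
  if (!is.null(masks)) {
    overlay <- df
    overlay$region <- NA_character_
    overlay$region[as.vector(masks$pm_annulus)] <- "PM annulus"
    overlay$region[as.vector(masks$interior)] <- "interior"
    overlay <- overlay[!is.na(overlay$region), ]
    p <- p + ggplot2::geom_raster(
      data = overlay,
      ggplot2::aes(.data$col, .data$row, alpha = .data$region),
      fill = "orangered", inherit.aes = FALSE
    ) +
      ggplot2::scale_alpha_manual(
        values = c("PM annulus" = 0.45, "interior" = 0.12), name = NULL
      )
  }
  p
}

#' Plot a sensorgram
#'
#' @param sensorgram sensorgram tibble (or list of them) with `time_s`,
#'   `response_RU`, `phase`, `conc_M`.
#' @return a ggplot object; curves are coloured by concentration and the
#'   association/dissociation boundary is marked.
#' @export
plot_sensorgram <- function(sensorgram) {
  if (!is.data.frame(sensorgram)) {
    sensorgram <- dplyr::bind_rows(sensorgram)
  }
  ggplot2::ggplot(
    sensorgram,
    ggplot2::aes(.data$time_s, .data$response_RU,
      colour = factor(.data$conc_M * 1e9), group = .data$conc_M
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "response (RU)", colour = "[P] (nM)"
    )
}

#' Bar chart of group means with SEM error bars
#'
#' @param summary_table output of [summarize_groups()].
#' @return a ggplot object.
#' @export
plot_group_summary <- function(summary_table) {
  ggplot2::ggplot(
    summary_table,
    ggplot2::aes(.data$group, .data$mean)
  ) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sem,
        ymax = .data$mean + .data$sem
      ),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "mean ± SEM")
}
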