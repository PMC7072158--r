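#' Render a synthetic fluorescent cell with known ground truth
#'
#' Paints an idealised adherent cell — a bright plasma-membrane rim around a
#' diffuse cytosol, optionally a dimmer nucleus and intracellular puncta — on
#' a flat background, then optionally corrupts it with the standard
#' fluorescence-camera noise model (Poisson on the signal, then additive
#' Gaussian read noise). The exact masks used to paint the cell are returned
#' alongside the analytic localization metrics they imply, so segmentation
#' and quantification can be validated against a known answer.
#'
#' The cell outline is a disc whose radius is modulated by a low-order
#' harmonic, `R(theta) = cell_radius * (1 + boundary_amp * cos(boundary_order
#' * theta))`, which mimics irregular cell shapes and exercises non-convex
#' erosion behaviour. The rim (annulus) is the band within `rim_width` of the
#' outline; everything deeper is interior.
#'
#' @param image_shape integer vector `c(rows, cols)` in pixels.
#' @param pixel_size pixel size in um/pixel. Default 0.1 um, typical of a
#'   zoomed 63x confocal scan.
#' @param cell_radius nominal cell radius in um.
#' @param rim_width plasma-membrane rim thickness in um (>= one pixel).
#' @param membrane_intensity,cytosol_intensity,background intensities in AFU.
#' @param nucleus_intensity optional nucleus intensity in AFU (`NULL` = no
#'   nucleus); the nucleus is a centred disc of `nucleus_radius` um.
#' @param nucleus_radius nucleus radius in um.
#' @param n_puncta number of intracellular puncta (painted strictly inside
#'   the interior mask so vesicle staining never contaminates the rim).
#' @param puncta_intensity punctum intensity in AFU.
#' @param puncta_radius punctum radius in um.
#' @param boundary_amp,boundary_order amplitude (fraction of radius) and
#'   angular order of the harmonic boundary perturbation; `boundary_amp = 0`
#'   gives a perfect disc.
#' @param poisson_noise logical; apply Poisson (shot) noise, treating AFU as
#'   photon counts.
#' @param gaussian_sd standard deviation of additive Gaussian read noise
#'   (AFU); 0 disables it.
#' @param seed integer seed for the noise and puncta placement; `NULL` uses
#'   (and advances) the current RNG state. Identical seeds and parameters
#'   give bit-identical images.
#'
#' @return a `synthetic_cell` list: `image` (noisy `cell_image`), `clean`
#'   (noiseless image), and `truth` with `i_pm`, `i_cyt`, `pm_index`,
#'   `percent_pm` computed from the noiseless painted pixels, plus the
#'   ground-truth `masks` (`cell_masks`).
#' @examples
#' cell <- simulate_cell(seed = 1)
#' cell$truth$percent_pm # 80: membrane 200 vs cytosol 50 AFU
#' @export
simulate_cell <- function(image_shape = c(128L, 128L),
                          pixel_size = 0.1,
                          cell_radius = 5,
                          rim_width = 0.4,
                          membrane_intensity = 200,
                          cytosol_intensity = 50,
                          background = 5,
                          nucleus_intensity = NULL,
                          nucleus_radius = 0.4 * cell_radius,
                          n_puncta = 0L,
                          puncta_intensity = 2 * cytosol_intensity,
                          puncta_radius = 0.2,
                          boundary_amp = 0.06,
                          boundary_order = 3L,
                          poisson_noise = TRUE,
                          gaussian_sd = 2,
                          seed = NULL) {
  check_cell_params(
    image_shape, pixel_size, cell_radius, rim_width,
    membrane_intensity, cytosol_intensity, background,
    nucleus_intensity, n_puncta, puncta_intensity, gaussian_sd,
    boundary_amp
  )

  geom <- cell_geometry(
    image_shape, pixel_size, cell_radius, rim_width,
    boundary_amp, boundary_order
  )

  with_optional_seed(seed, {
    clean <- paint_cell(
      geom, membrane_intensity, cytosol_intensity, background,
      nucleus_intensity, nucleus_radius, n_puncta, puncta_intensity,
      puncta_radius, pixel_size
    )
    noisy <- add_camera_noise(clean, poisson_noise, gaussian_sd)

    i_pm <- mean(clean[geom$pm_annulus])
    i_cyt <- mean(clean[geom$interior])
    masks <- cell_masks(geom$cell, geom$pm_annulus, geom$interior,
      n_erosions_used = round(rim_width / pixel_size)
    )

    structure(
      list(
        image = cell_image(noisy, pixel_size, channel = "mCherry"),
        clean = cell_image(clean, pixel_size, channel = "mCherry"),
        truth = list(
          i_pm = i_pm, i_cyt = i_cyt,
          pm_index = i_pm / i_cyt,
          percent_pm = 100 * i_pm / (i_pm + i_cyt),
          masks = masks
        )
      ),
      class = "synthetic_cell"
    )
  })
}

#' Render a synthetic phosphatase-recruitment time-lapse
#'
#' Emulates a rapamycin-induced phosphoinositide-depletion experiment: after
#' recruitment of a membrane-targeted phosphatase, the probe's membrane
#' signal decays exponentially toward the cytosol-equilibrated level,
#' `M(t) = C0 + (M0 - C0) * exp(-pm_decay_rate * t)`. With `cytosol_gain`
#' the fluorescence lost from the rim reappears in the cytosol so total
#' painted signal is conserved frame to frame (before noise), as it is for a
#' probe that merely translocates.
#'
#' @inheritParams simulate_cell
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds between frames; the default 5 s matches
#'   typical live-cell scan cadence over a 5-min treatment.
#' @param pm_decay_rate membrane-dissociation rate in 1/s (>= 0; 0 = no
#'   change, e.g. a catalytically dead phosphatase control).
#' @param cytosol_gain logical; conserve translocated signal in the cytosol.
#' @param ... further parameters passed to the per-frame cell renderer
#'   (intensities, noise, geometry; see [simulate_cell()]).
#'
#' @return a `synthetic_timeseries` list: `frames` (list of `cell_image`),
#'   `times` (s), and `truth` with the per-frame noiseless `pm_index` vector,
#'   the `dissociation_index` (first-frame PM index over last-frame PM
#'   index), and the shared ground-truth `masks`.
#' @examples
#' ts <- simulate_timeseries(n_frames = 3, pm_decay_rate = 0, seed = 1)
#' ts$truth$dissociation_index # 1: no decay
#' @export
simulate_timeseries <- function(n_frames = 10L,
                                frame_interval = 5,
                                pm_decay_rate = 0.01,
                                cytosol_gain = TRUE,
                                image_shape = c(128L, 128L),
                                pixel_size = 0.1,
                                cell_radius = 5,
                                rim_width = 0.4,
                                membrane_intensity = 200,
                                cytosol_intensity = 50,
                                background = 5,
                                boundary_amp = 0.06,
                                boundary_order = 3L,
                                poisson_noise = TRUE,
                                gaussian_sd = 2,
                                seed = NULL) {
  if (n_frames < 2L) abort("`n_frames` must be at least 2.")
  if (pm_decay_rate < 0) abort("`pm_decay_rate` must be >= 0.")
  if (frame_interval <= 0) abort("`frame_interval` must be > 0.")

  geom <- cell_geometry(
    image_shape, pixel_size, cell_radius, rim_width,
    boundary_amp, boundary_order
  )
  a_m <- sum(geom$pm_annulus)
  a_c <- sum(geom$interior)
  times <- (seq_len(n_frames) - 1) * frame_interval

  m_t <- cytosol_intensity +
    (membrane_intensity - cytosol_intensity) * exp(-pm_decay_rate * times)
  c_t <- if (cytosol_gain) {
    cytosol_intensity + (a_m / a_c) * (membrane_intensity - m_t)
  } else {
    rep(cytosol_intensity, n_frames)
  }

  with_optional_seed(seed, {
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      clean <- paint_cell(
        geom, m_t[k], c_t[k], background,
        nucleus_intensity = NULL, nucleus_radius = 0,
        n_puncta = 0L, puncta_intensity = 0, puncta_radius = 0,
        pixel_size = pixel_size
      )
      noisy <- add_camera_noise(clean, poisson_noise, gaussian_sd)
      frames[[k]] <- cell_image(noisy, pixel_size,
        channel = "mCherry", time_index = k
      )
    }
    idx <- m_t / c_t
    masks <- cell_masks(geom$cell, geom$pm_annulus, geom$interior,
      n_erosions_used = round(rim_width / pixel_size)
    )
    structure(
      list(
        frames = frames, times = times,
        truth = list(
          pm_index = idx,
          dissociation_index = idx[1] / idx[n_frames],
          membrane_intensity = m_t, cytosol_intensity = c_t,
          masks = masks
        )
      ),
      class = "synthetic_timeseries"
    )
  })
}

# ---- internals --------------------------------------------------------------

check_cell_params <- function(image_shape, pixel_size, cell_radius, rim_width,
                              membrane_intensity, cytosol_intensity, background,
                              nucleus_intensity, n_puncta, puncta_intensity,
                              gaussian_sd, boundary_amp) {
  if (length(image_shape) != 2L || any(image_shape < 8)) {
    abort("`image_shape` must be two values, each >= 8.")
  }
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  if (cell_radius <= 0) abort("`cell_radius` must be > 0.")
  if (rim_width < pixel_size) {
    abort("`rim_width` must be at least one pixel (`pixel_size`).")
  }
  ints <- c(
    membrane_intensity, cytosol_intensity, background,
    nucleus_intensity %||% 0, puncta_intensity, gaussian_sd
  )
  if (any(ints < 0)) abort("intensities and noise levels must be >= 0.")
  if (n_puncta < 0) abort("`n_puncta` must be >= 0.")
  if (boundary_amp < 0 || boundary_amp >= 1) {
    abort("`boundary_amp` must be in [0, 1).")
  }
  invisible(TRUE)
}

# Geometry (cell / rim / interior masks) shared by single images and stacks.
cell_geometry <- function(image_shape, pixel_size, cell_radius, rim_width,
                          boundary_amp, boundary_order) {
  nr <- image_shape[1]
  nc <- image_shape[2]
  max_r_px <- cell_radius * (1 + boundary_amp) / pixel_size
  if (max_r_px > min(nr, nc) / 2 - 2) {
    abort(sprintf(
      "geometry error: cell of max radius %.1f px does not fit a %d x %d frame.",
      max_r_px, nr, nc
    ))
  }
  cx <- (nr + 1) / 2
  cy <- (nc + 1) / 2
  dx <- matrix(seq_len(nr) - cx, nr, nc)
  dy <- matrix(seq_len(nc) - cy, nr, nc, byrow = TRUE)
  r_um <- sqrt(dx^2 + dy^2) * pixel_size
  theta <- atan2(dy, dx)
  r_cell <- cell_radius * (1 + boundary_amp * cos(boundary_order * theta))

  cell <- r_um <= r_cell
  interior <- r_um <= r_cell - rim_width
  list(
    cell = cell, interior = interior, pm_annulus = cell & !interior,
    r_um = r_um, dx = dx, dy = dy
  )
}

paint_cell <- function(geom, membrane_intensity, cytosol_intensity, background,
                       nucleus_intensity, nucleus_radius, n_puncta,
                       puncta_intensity, puncta_radius, pixel_size) {
  img <- matrix(background, nrow(geom$cell), ncol(geom$cell))
  img[geom$interior] <- cytosol_intensity
  img[geom$pm_annulus] <- membrane_intensity

  if (!is.null(nucleus_intensity)) {
    nucleus <- geom$r_um <= nucleus_radius
    img[nucleus & geom$interior] <- nucleus_intensity
  }
  if (n_puncta > 0L) {
    centers <- which(geom$interior, arr.ind = TRUE)
    pick <- centers[sample.int(nrow(centers), n_puncta, replace = TRUE), ,
      drop = FALSE
    ]
    r_px <- max(1, puncta_radius / pixel_size)
    for (p in seq_len(n_puncta)) {
      d2 <- (geom$dx - (pick[p, 1] - (nrow(img) + 1) / 2))^2 +
        (geom$dy - (pick[p, 2] - (ncol(img) + 1) / 2))^2
      spot <- d2 <= r_px^2
      img[spot & geom$interior] <- puncta_intensity
    }
  }
  img
}

add_camera_noise <- function(img, poisson_noise, gaussian_sd) {
  out <- img
  if (isTRUE(poisson_noise)) {
    out[] <- rpois(length(out), lambda = out)
  }
  if (gaussian_sd > 0) {
    out <- out + rnorm(length(out), sd = gaussian_sd)
  }
  pmax(out, 0)
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
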