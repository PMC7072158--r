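#' Simulate a 1:1 Langmuir SPR sensorgram
#'
#' Generates an association/dissociation sensorgram from the single-site
#' Langmuir model used for protein-vesicle surface plasmon resonance.
#' During association at analyte concentration `[P]`,
#' `R(t) = Req * (1 - exp(-(ka*[P] + kd) * t))` with
#' `Req = Rmax * [P] / ([P] + kd/ka)`; after the injection stops the bound
#' response decays as `R(t_assoc + s) = R(t_assoc) * exp(-kd * s)`.
#' Optional Gaussian noise and a linear baseline drift emulate instrument
#' imperfections.
#'
#' @param ka association rate constant, 1/(M s).
#' @param kd dissociation rate constant, 1/s.
#' @param Rmax maximal response at surface saturation, RU.
#' @param conc analyte (protein) concentration `[P]`, M.
#' @param t_assoc,t_dissoc association and dissociation durations, s
#'   (a 150 s dissociation window is typical of vesicle-capture assays).
#' @param sampling_rate samples per second, Hz.
#' @param noise_sd Gaussian noise standard deviation, RU (0 = noiseless).
#' @param drift linear baseline drift, RU/s.
#' @param seed integer seed; `NULL` uses the current RNG state.
#'
#' @return a tibble with columns `time_s`, `response_RU`, `phase`
#'   (`"association"`/`"dissociation"`) and `conc_M`; the generating
#'   parameters are attached as attribute `params`.
#' @examples
#' sg <- simulate_sensorgram(
#'   ka = 1e5, kd = 0.01, Rmax = 100,
#'   conc = 500e-9, noise_sd = 0
#' )
#' @export
simulate_sensorgram <- function(ka, kd, Rmax, conc,
                                t_assoc = 300, t_dissoc = 150,
                                sampling_rate = 1, noise_sd = 0,
                                drift = 0, seed = NULL) {
  if (any(c(ka, kd, Rmax, conc, t_assoc, t_dissoc, sampling_rate) <= 0)) {
    abort("ka, kd, Rmax, conc, durations and sampling_rate must all be > 0.")
  }
  kobs <- ka * conc + kd
  req <- Rmax * conc / (conc + kd / ka)

  t_a <- seq(0, t_assoc, by = 1 / sampling_rate)
  r_a <- req * (1 - exp(-kobs * t_a))
  r_end <- r_a[length(r_a)]
  t_d <- seq(1 / sampling_rate, t_dissoc, by = 1 / sampling_rate)
  r_d <- r_end * exp(-kd * t_d)

  time <- c(t_a, t_assoc + t_d)
  resp <- c(r_a, r_d) + drift * time
  resp <- with_optional_seed(seed, {
    if (noise_sd > 0) resp + rnorm(length(resp), sd = noise_sd) else resp
  })

  out <- tibble::tibble(
    time_s = time,
    response_RU = resp,
    phase = rep(c("association", "dissociation"), c(length(t_a), length(t_d))),
    conc_M = conc
  )
  attr(out, "params") <- list(
    ka = ka, kd = kd, Rmax = Rmax, conc = conc, Req = req, kobs = kobs,
    t_assoc = t_assoc, t_dissoc = t_dissoc
  )
  out
}

#' Simulate saturation (equilibrium) SPR responses
#'
#' Draws equilibrium responses from the Langmuir binding isotherm
#' `Req = Rmax / (1 + Kd/[P])` at the given analyte concentrations, with
#' optional additive Gaussian noise.
#'
#' @param Kd apparent dissociation constant, M.
#' @param Rmax maximal response, RU.
#' @param concs vector of analyte concentrations, M (nonempty, > 0).
#' @param noise_sd Gaussian noise standard deviation, RU.
#' @param seed integer seed; `NULL` uses the current RNG state.
#'
#' @return a tibble with columns `conc_M` and `Req_RU`.
#' @examples
#' simulate_isotherm(Kd = 250e-9, Rmax = 80, concs = c(0.1, 0.25, 1, 3) * 1e-6)
#' @export
simulate_isotherm <- function(Kd, Rmax, concs, noise_sd = 0, seed = NULL) {
  if (length(concs) == 0 || any(concs <= 0)) {
    abort("`concs` must be a nonempty vector of positive concentrations.")
  }
  if (Kd <= 0 || Rmax <= 0) abort("`Kd` and `Rmax` must be > 0.")
  req <- Rmax / (1 + Kd / concs)
  req <- with_optional_seed(seed, {
    if (noise_sd > 0) req + rnorm(length(req), sd = noise_sd) else req
  })
  tibble::tibble(conc_M = as.numeric(concs), Req_RU = req)
}

#' Simulate a co-sedimentation gel lane
#'
#' Emulates densitometry of a liposome pelleting assay: total protein
#' density splits between the pellet (vesicle-bound, `total *
#' bound_fraction`) and the supernatant (unbound, the remainder), with
#' optional Gaussian densitometry noise; densities are clipped at zero.
#'
#' @param total_density total band density, arbitrary densitometry units.
#' @param bound_fraction fraction of protein pelleting with the vesicles,
#'   in `[0, 1]`.
#' @param noise_sd Gaussian noise standard deviation (AU) applied
#'   independently to each band.
#' @param lane lane label.
#' @param seed integer seed; `NULL` uses the current RNG state.
#'
#' @return a one-row tibble with columns `lane`, `supernatant`, `pellet`.
#' @examples
#' simulate_gel_lane(1000, bound_fraction = 0.25)
#' @export
simulate_gel_lane <- function(total_density, bound_fraction, noise_sd = 0,
                              lane = "lane1", seed = NULL) {
  if (bound_fraction < 0 || bound_fraction > 1) {
    abort("`bound_fraction` must be in [0, 1].")
  }
  if (total_density < 0) abort("`total_density` must be >= 0.")
  pellet <- total_density * bound_fraction
  supernatant <- total_density * (1 - bound_fraction)
  if (noise_sd > 0) {
    noise <- with_optional_seed(seed, rnorm(2, sd = noise_sd))
    supernatant <- supernatant + noise[1]
    pellet <- pellet + noise[2]
  }
  tibble::tibble(
    lane = lane,
    supernatant = max(supernatant, 0),
    pellet = max(pellet, 0)
  )
}
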