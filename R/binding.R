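#' Percent binding from co-sedimentation densitometry
#'
#' In a liposome pelleting assay the vesicle-bound protein sediments with
#' the pellet and unbound protein stays in the supernatant; densitometry of
#' the two gel bands gives the bound percentage,
#' `raw = 100 * pellet / (pellet + supernatant)`. The ratio is invariant to
#' overall gel exposure (multiplying both bands by any positive constant).
#' When a control lane (protein spun with plain carrier vesicles) is
#' supplied, its raw percentage is subtracted and the result floored at
#' zero, expressing binding with respect to control vesicles.
#'
#' @param lanes tibble/data frame of lanes with columns `lane`,
#'   `supernatant`, `pellet` (densitometry AU; see [simulate_gel_lane()]).
#' @param control `NULL` for raw percentages; a lane id present in
#'   `lanes$lane`, or a one-row data frame with `supernatant` and `pellet`,
#'   to correct against.
#'
#' @return the input tibble with `percent_bound` added (and
#'   `percent_bound_raw` when a control is applied; control rows keep their
#'   raw value).
#' @examples
#' lane <- simulate_gel_lane(1000, bound_fraction = 0.25)
#' percent_binding(lane)$percent_bound # 25
#' @export
percent_binding <- function(lanes, control = NULL) {
  lanes <- tibble::as_tibble(lanes)
  req <- c("supernatant", "pellet")
  if (!all(req %in% names(lanes))) {
    abort("`lanes` needs columns `supernatant` and `pellet`.")
  }
  total <- lanes$supernatant + lanes$pellet
  if (any(lanes$supernatant < 0 | lanes$pellet < 0)) {
    abort("band densities must be >= 0.")
  }
  if (any(total <= 0)) {
    abort("zero total density: supernatant + pellet must be > 0 in every lane.")
  }
  raw <- 100 * lanes$pellet / total

  if (is.null(control)) {
    lanes$percent_bound <- raw
    return(lanes)
  }

  raw_control <- if (is.character(control) && length(control) == 1L) {
    hit <- lanes$lane == control
    if (!any(hit)) abort(sprintf("control lane '%s' not found.", control))
    raw[hit][1]
  } else if (is.data.frame(control) && nrow(control) == 1L) {
    tot <- control$supernatant + control$pellet
    if (tot <= 0) abort("zero total density in control lane.")
    100 * control$pellet / tot
  } else {
    abort("`control` must be NULL, a lane id, or a one-row data frame.")
  }

  lanes$percent_bound_raw <- raw
  lanes$percent_bound <- pmax(raw - raw_control, 0)
  if (is.character(control)) {
    lanes$percent_bound[lanes$lane == control] <- raw[lanes$lane == control]
  }
  lanes
}

#' Headgroup-charge proxy table for phosphoinositide classes
#'
#' Vesicle compositions that compare phosphoinositide (PIP) classes at
#' equivalent total headgroup charge need a per-class charge value. The
#' default proxy counts ring phosphomonoesters (mono-, bis-,
#' tris-phosphorylated inositol = 1, 2, 3); this is the convention that
#' makes 5 mol% of a bisphosphate PIP charge-equivalent to 3.3 mol% of
#' PIP3. A physiological per-headgroup net-charge table (approximate values
#' at pH 7.4) is available as an alternative.
#'
#' @param model `"phosphate_count"` (default) or `"physiological"`.
#' @return named numeric vector over classes `mono`, `bis`, `tris`.
#' @export
pip_charge_table <- function(model = c("phosphate_count", "physiological")) {
  model <- match.arg(model)
  switch(model,
    phosphate_count = c(mono = 1, bis = 2, tris = 3),
    physiological = c(mono = -3, bis = -4, tris = -6)
  )
}

#' Charge-matched mol% for a phosphoinositide swap
#'
#' Given a reference PIP class at a reference mol%, returns the mol% of a
#' target class carrying the same total headgroup charge:
#' `ref_molpct * charge(ref) / charge(target)`, reported to one decimal.
#' Mapping A to B and back returns the original value (up to rounding).
#'
#' @param ref_class,target_class PIP classes present in `charge_table`
#'   (default classes: `"mono"`, `"bis"`, `"tris"`).
#' @param ref_molpct reference mol% (> 0).
#' @param charge_table named charge vector; see [pip_charge_table()].
#' @param digits decimals in the reported mol%.
#'
#' @return target mol% (numeric).
#' @examples
#' charge_matched_molpercent("bis", 5, "tris") # 3.3
#' @export
charge_matched_molpercent <- function(ref_class, ref_molpct, target_class,
                                      charge_table = pip_charge_table(),
                                      digits = 1) {
  for (cls in c(ref_class, target_class)) {
    if (!cls %in% names(charge_table)) {
      abort(sprintf(
        "unknown PIP class '%s'; charge table knows: %s.",
        cls, paste(names(charge_table), collapse = ", ")
      ))
    }
  }
  if (ref_molpct <= 0) abort("`ref_molpct` must be > 0.")
  round(ref_molpct * charge_table[[ref_class]] / charge_table[[target_class]],
    digits = digits
  )
}

#' Validate a vesicle lipid composition
#'
#' @param species named numeric vector or data frame (`species`, `mol_pct`)
#'   of mol percentages; values must be nonnegative and sum to 100 within
#'   0.1.
#' @return a tibble with columns `species` and `mol_pct`.
#' @examples
#' lipid_composition(c(POPC = 75, POPE = 20, `PI(4,5)P2` = 5))
#' @export
lipid_composition <- function(species) {
  if (is.data.frame(species)) {
    comp <- tibble::as_tibble(species)
    if (!all(c("species", "mol_pct") %in% names(comp))) {
      abort("data-frame input needs columns `species` and `mol_pct`.")
    }
  } else if (is.numeric(species) && !is.null(names(species))) {
    vals <- as.numeric(species)
    comp <- tibble::tibble(species = names(species), mol_pct = vals)
  } else {
    abort("`species` must be a named numeric vector or a data frame.")
  }
  if (any(comp$mol_pct < 0)) abort("mol%% values must be >= 0.")
  tot <- sum(comp$mol_pct)
  if (abs(tot - 100) > 0.1) {
    abort(sprintf("mol%% must sum to 100 +/- 0.1 (got %.2f).", tot))
  }
  comp
}

#' Subtract a control-surface sensorgram
#'
#' Corrects an active-surface sensorgram for refractive-index changes and
#' non-specific binding by pointwise subtraction of the control (carrier
#' lipid) channel. If the control was sampled on a staggered time grid it
#' is linearly interpolated onto the active grid; active time points
#' outside the control's range (beyond `tol` seconds) are an error.
#'
#' @param active,control sensorgram tibbles (`time_s`, `response_RU`, ...).
#' @param tol tolerated extrapolation at the grid ends, s.
#' @return the `active` tibble with `response_RU` replaced by the corrected
#'   response; phase labels are preserved.
#' @export
subtract_control <- function(active, control, tol = 0.5) {
  for (df in list(active, control)) {
    if (!all(c("time_s", "response_RU") %in% names(df))) {
      abort("sensorgrams need columns `time_s` and `response_RU`.")
    }
  }
  rng <- range(control$time_s)
  out_of_range <- active$time_s < rng[1] - tol | active$time_s > rng[2] + tol
  if (any(out_of_range)) {
    abort("non-overlapping time ranges: control does not cover the active sensorgram.")
  }
  ctrl_resp <- approx(control$time_s, control$response_RU,
    xout = active$time_s, rule = 2
  )$y
  active$response_RU <- active$response_RU - ctrl_resp
  active
}

#' Equilibrium response from the association plateau
#'
#' Estimates the saturation response `Req` as the mean response over the
#' final `window` seconds of the association phase. The default window is
#' the last 10% of the phase (at least 5 samples). On a curve still rising
#' at the end of the injection this plateau mean underestimates the true
#' asymptote; use association times long relative to `1/kobs`.
#'
#' @param sensorgram sensorgram tibble with a `phase` column.
#' @param window averaging window in seconds; `NULL` for the default.
#' @return the estimated `Req` in RU.
#' @examples
#' sg <- simulate_sensorgram(ka = 1e5, kd = 0.01, Rmax = 100, conc = 1e-6)
#' extract_Req(sg)
#' @export
extract_Req <- function(sensorgram, window = NULL) {
  if (!all(c("time_s", "response_RU", "phase") %in% names(sensorgram))) {
    abort("sensorgram needs columns `time_s`, `response_RU`, `phase`.")
  }
  assoc <- sensorgram[sensorgram$phase == "association", ]
  if (nrow(assoc) < 2L) abort("association phase has too few samples.")
  duration <- diff(range(assoc$time_s))
  dt <- stats::median(diff(sort(assoc$time_s)))
  if (is.null(window)) {
    window <- max(0.1 * duration, 5 * dt)
  }
  if (window > duration) {
    abort("`window` exceeds the association phase duration.")
  }
  t_end <- max(assoc$time_s)
  mean(assoc$response_RU[assoc$time_s >= t_end - window])
}
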