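test_that("percent binding follows the pellet fraction and is scale-invariant", {
  lanes <- tibble::tibble(
    lane = c("all", "half"),
    supernatant = c(0, 300),
    pellet = c(500, 300)
  )
  out <- percent_binding(lanes)
  expect_equal(out$percent_bound, c(100, 50))

  # generator/metric round trip at a known bound fraction
  lane <- simulate_gel_lane(1000, bound_fraction = 0.25)
  expect_equal(percent_binding(lane)$percent_bound, 25)

  for (k in c(0.01, 3, 250)) {
    scaled <- lanes
    scaled$supernatant <- scaled$supernatant * k
    scaled$pellet <- scaled$pellet * k
    expect_equal(percent_binding(scaled)$percent_bound, out$percent_bound)
  }

  expect_error(
    percent_binding(tibble::tibble(lane = "x", supernatant = 0, pellet = 0)),
    "zero total"
  )
})

test_that("control-lane correction subtracts the control percentage, floored at zero", {
  lanes <- dplyr::bind_rows(
    simulate_gel_lane(1000, 0.10, lane = "control"),
    simulate_gel_lane(1000, 0.35, lane = "PS"),
    simulate_gel_lane(1000, 0.05, lane = "weak")
  )
  out <- percent_binding(lanes, control = "control")
  expect_equal(out$percent_bound[out$lane == "PS"], 25)
  expect_equal(out$percent_bound[out$lane == "weak"], 0) # floored
  expect_error(percent_binding(lanes, control = "nope"), "not found")
})

test_that("charge-matched mol% reproduces the bis/tris design and is involutive", {
  expect_equal(charge_matched_molpercent("bis", 5, "tris"), 3.3)
  expect_equal(charge_matched_molpercent("bis", 5, "bis"), 5)
  expect_equal(charge_matched_molpercent("mono", 5, "tris"), 1.7)

  classes <- names(pip_charge_table())
  for (a in classes) {
    for (b in classes) {
      fwd <- charge_matched_molpercent(a, 5, b)
      back <- charge_matched_molpercent(b, fwd, a)
      expect_lt(abs(back - 5), 0.1 + 1e-9)
    }
  }

  # the physiological table preserves the qualitative ordering
  phys <- pip_charge_table("physiological")
  expect_lt(
    charge_matched_molpercent("bis", 5, "tris", charge_table = phys), 5
  )
  expect_error(charge_matched_molpercent("hexakis", 5, "tris"), "unknown")
})

test_that("lipid compositions must sum to 100", {
  comp <- lipid_composition(c(POPC = 75, POPE = 20, PIP2 = 5))
  expect_equal(sum(comp$mol_pct), 100)
  expect_error(lipid_composition(c(POPC = 75, POPE = 20)), "sum to 100")
  expect_error(lipid_composition(c(POPC = 105, POPE = -5)), "0")
})

test_that("control subtraction removes shared signal and handles staggered grids", {
  sg <- simulate_sensorgram(1e5, 0.01, 100, 1e-6, noise_sd = 0)
  zero <- subtract_control(sg, sg)
  expect_true(all(abs(zero$response_RU) < 1e-12))
  expect_identical(zero$phase, sg$phase)

  ctrl <- sg
  ctrl$response_RU <- 7
  shifted <- subtract_control(sg, ctrl)
  expect_equal(shifted$response_RU, sg$response_RU - 7)

  # control sampled on a staggered, denser grid: the corrected trace must
  # equal the analytic difference of the two generating models
  active <- simulate_sensorgram(1e5, 0.01, 100, 1e-6,
    t_assoc = 100, t_dissoc = 50, sampling_rate = 1, noise_sd = 0
  )
  control <- simulate_sensorgram(5e4, 0.05, 30, 1e-6,
    t_assoc = 100, t_dissoc = 50, sampling_rate = 4, noise_sd = 0
  )
  control$time_s <- control$time_s + 0.125 # stagger
  corrected <- subtract_control(active, control, tol = 0.5)
  model_ctrl <- function(t) {
    kobs <- 5e4 * 1e-6 + 0.05
    req <- 30 * 1e-6 / (1e-6 + 0.05 / 5e4)
    r_end <- req * (1 - exp(-kobs * 100))
    ifelse(t <= 100, req * (1 - exp(-kobs * t)), r_end * exp(-0.05 * (t - 100)))
  }
  analytic <- active$response_RU - model_ctrl(active$time_s)
  expect_equal(corrected$response_RU, analytic, tolerance = 1e-3)

  late <- active
  late$time_s <- late$time_s + 1000
  expect_error(subtract_control(late, control), "non-overlapping")
})

test_that("Req extraction averages the association plateau", {
  sg <- simulate_sensorgram(1e5, 0.01, 100, 2e-6,
    t_assoc = 300, noise_sd = 0
  )
  req_true <- attr(sg, "params")$Req
  expect_equal(extract_Req(sg), req_true, tolerance = 0.01)

  flat <- tibble::tibble(
    time_s = 0:100, response_RU = 42,
    phase = "association", conc_M = 1e-6
  )
  expect_equal(extract_Req(flat), 42)

  # window covering a still-rising curve underestimates the asymptote
  rising <- simulate_sensorgram(1e5, 0.01, 100, 2e-6,
    t_assoc = 10, noise_sd = 0
  )
  expect_lt(extract_Req(rising, window = 10), req_true)

  expect_error(extract_Req(sg, window = 1000), "exceeds")
})

test_that("isotherm fitting recovers generating parameters from noiseless data", {
  concs <- c(10, 30, 100, 250, 500, 1000, 2000, 3000) * 1e-9
  iso <- simulate_isotherm(Kd = 250e-9, Rmax = 80, concs = concs)
  fit <- fit_isotherm(iso)
  expect_equal(fit$Kd, 250e-9, tolerance = 1e-6)
  expect_equal(fit$Rmax, 80, tolerance = 1e-6)
  expect_true(fit$converged)
  # model identity: at [P] = fitted Kd the fitted curve sits at Rmax/2
  at_kd <- fit$Rmax / (1 + fit$Kd / fit$Kd)
  expect_equal(at_kd, fit$Rmax / 2)

  td <- tidy(fit)
  expect_identical(td$term, c("Kd", "Rmax"))
  expect_equal(td$estimate[1], fit$Kd)
  expect_true(all(is.finite(td$std.error)))
  g <- glance(fit)
  expect_lt(g$rss, 1e-12)
})

test_that("with Rmax fixed, a half-maximal point pins Kd at that concentration", {
  iso <- tibble::tibble(conc_M = 400e-9, Req_RU = 50)
  fit <- fit_isotherm(iso, fix_Rmax = 100)
  expect_equal(fit$Kd, 400e-9, tolerance = 1e-6)
  expect_true(fit$fixed_Rmax)
})

test_that("isotherm fit warns when concentrations do not span Kd", {
  concs <- c(1, 2, 4, 8) * 1e-9 # far below Kd = 1 uM
  iso <- simulate_isotherm(Kd = 1e-6, Rmax = 100, concs = concs)
  expect_warning(fit_isotherm(iso), "ill-conditioned")
  expect_error(fit_isotherm(iso[1:2, ]), "3 distinct")
})

test_that("kinetic fits recover ka and kd from noiseless Langmuir sensorgrams", {
  ka <- 1e5
  kd <- 0.01
  Kd <- kd / ka # 100 nM
  sgs <- lapply(c(1, 2, 4) * Kd, function(cc) {
    simulate_sensorgram(ka, kd, 100, cc,
      t_assoc = 400, t_dissoc = 200, noise_sd = 0
    )
  })
  fit <- fit_kinetics(sgs)
  expect_equal(fit$ka, ka, tolerance = 1e-4)
  expect_equal(fit$kd, kd, tolerance = 1e-4)
  # kobs regression intercept is an independent estimate of kd
  expect_equal(fit$kobs_intercept, kd, tolerance = 1e-3)
  expect_equal(fit$per_curve$kobs, ka * c(1, 2, 4) * Kd + kd, tolerance = 1e-4)
  # invariant: kobs >= kd for every curve
  expect_true(all(fit$per_curve$kobs >= fit$kd - 1e-9))

  expect_error(fit_kinetics(sgs[1]), "2 distinct")
})

test_that("a pure exponential dissociation yields its decay rate exactly", {
  sg <- simulate_sensorgram(1e5, 0.01, 100, 1e-6,
    t_assoc = 600, t_dissoc = 300, noise_sd = 0
  )
  sg2 <- simulate_sensorgram(1e5, 0.01, 100, 2e-6,
    t_assoc = 600, t_dissoc = 300, noise_sd = 0
  )
  fit <- fit_kinetics(list(sg, sg2))
  expect_equal(fit$per_curve$kd_curve, c(0.01, 0.01), tolerance = 1e-6)
})

test_that("kinetic and equilibrium routes agree on noiseless data", {
  ka <- 2e5
  kd <- 0.02
  Kd <- kd / ka
  sgs <- lapply(c(0.5, 1, 2, 4) * Kd, function(cc) {
    simulate_sensorgram(ka, kd, 100, cc,
      t_assoc = 1500, t_dissoc = 200, noise_sd = 0
    )
  })
  kin <- fit_kinetics(sgs)

  concs <- Kd * c(0.1, 0.25, 0.5, 1, 2, 4, 8, 16)
  iso <- simulate_isotherm(Kd = Kd, Rmax = 100, concs = concs)
  eq <- fit_isotherm(iso)
  expect_equal(kin$kd / kin$ka, eq$Kd, tolerance = 1e-3)
})
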