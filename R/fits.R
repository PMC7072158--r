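#' Fit the Langmuir binding isotherm
#'
#' Nonlinear least-squares fit of the single-site saturation isotherm
#' `Req = Rmax / (1 + Kd/[P])` to equilibrium SPR responses, estimating the
#' apparent dissociation constant `Kd` and the maximal response `Rmax`.
#'
#' Initialisation is data-driven: `Rmax` starts at 1.1 x the largest
#' response and `Kd` at the concentration whose response is closest to half
#' of that; both parameters are bounded above zero. If the tested
#' concentrations do not span the fitted `Kd` the problem is
#' ill-conditioned and a warning is raised — the estimates then come with
#' wide standard errors and should be read as bounds.
#'
#' @param data tibble with columns `conc_M` and `Req_RU` (see
#'   [simulate_isotherm()], [extract_Req()]).
#' @param init optional list with elements `Kd` and/or `Rmax` overriding
#'   the default start values.
#' @param fix_Rmax fix `Rmax` at this value and fit only `Kd` (then a
#'   single concentration suffices).
#'
#' @return an `isotherm_fit` object with elements `Kd`, `Rmax`, `se`
#'   (named standard errors), `rss`, `converged`, `data` and the underlying
#'   `nls` fit. Use [tidy()] / [glance()] / [autoplot()] on it.
#' @examples
#' iso <- simulate_isotherm(Kd = 250e-9, Rmax = 80,
#'   concs = c(10, 30, 100, 250, 500, 1000, 2000, 3000) * 1e-9)
#' fit_isotherm(iso)
#' @export
fit_isotherm <- function(data, init = NULL, fix_Rmax = NULL) {
  data <- tibble::as_tibble(data)
  if (!all(c("conc_M", "Req_RU") %in% names(data))) {
    abort("`data` needs columns `conc_M` and `Req_RU`.")
  }
  n_distinct <- length(unique(data$conc_M))
  if (is.null(fix_Rmax) && n_distinct < 3L) {
    abort("need at least 3 distinct concentrations to fit Kd and Rmax.")
  }
  if (any(data$conc_M <= 0)) abort("concentrations must be > 0.")

  rmax0 <- init$Rmax %||% (1.1 * max(data$Req_RU))
  kd0 <- init$Kd %||%
    data$conc_M[which.min(abs(data$Req_RU - rmax0 / 2))]
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14, maxiter = 500)

  if (is.null(fix_Rmax)) {
    fit <- minpack.lm::nlsLM(
      Req_RU ~ Rmax / (1 + Kd / conc_M),
      data = data,
      start = list(Rmax = rmax0, Kd = kd0),
      lower = c(Rmax = 1e-12, Kd = 1e-15),
      control = ctrl
    )
    est <- coef(fit)
    kd <- unname(est["Kd"])
    rmax <- unname(est["Rmax"])
  } else {
    Rmax_fixed <- fix_Rmax
    fit <- minpack.lm::nlsLM(
      Req_RU ~ Rmax_fixed / (1 + Kd / conc_M),
      data = data,
      start = list(Kd = kd0),
      lower = c(Kd = 1e-15),
      control = ctrl
    )
    kd <- unname(coef(fit)["Kd"])
    rmax <- fix_Rmax
  }

  se <- tryCatch(
    summary(fit)$coefficients[, "Std. Error"],
    error = function(e) NULL
  )
  if (!is.null(se)) se <- setNames(as.numeric(se), rownames(summary(fit)$coefficients))
  rss <- sum(stats::resid(fit)^2)

  if (max(data$conc_M) < kd) {
    warn("tested concentrations do not span the fitted Kd; the fit is ill-conditioned and standard errors are wide.")
  }

  structure(
    list(
      Kd = kd, Rmax = rmax, se = se, rss = rss,
      converged = fit$convInfo$isConv %||% TRUE,
      fixed_Rmax = !is.null(fix_Rmax),
      data = data, fit = fit
    ),
    class = "isotherm_fit"
  )
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf(
    "<isotherm_fit> Kd = %.4g M (%.4g nM), Rmax = %.4g RU%s, RSS = %.3g, n = %d\n",
    x$Kd, x$Kd * 1e9, x$Rmax, if (x$fixed_Rmax) " (fixed)" else "",
    x$rss, nrow(x$data)
  ))
  invisible(x)
}

#' @rdname fit_isotherm
#' @param x,object an `isotherm_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.isotherm_fit <- function(x, ...) {
  terms <- c("Kd", "Rmax")
  tibble::tibble(
    term = terms,
    estimate = c(x$Kd, x$Rmax),
    std.error = vapply(terms, function(t) {
      if (!is.null(x$se) && t %in% names(x$se)) x$se[[t]] else NA_real_
    }, numeric(1))
  )
}

#' @rdname fit_isotherm
#' @exportS3Method generics::glance
glance.isotherm_fit <- function(x, ...) {
  tibble::tibble(
    Kd = x$Kd, Rmax = x$Rmax, rss = x$rss,
    n = nrow(x$data), converged = x$converged
  )
}

#' @rdname fit_isotherm
#' @exportS3Method ggplot2::autoplot
autoplot.isotherm_fit <- function(object, ...) {
  grid <- tibble::tibble(
    conc_M = exp(seq(log(min(object$data$conc_M)),
      log(max(object$data$conc_M)),
      length.out = 200
    ))
  )
  grid$Req_RU <- object$Rmax / (1 + object$Kd / grid$conc_M)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$conc_M, .data$Req_RU)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "[P] (M)", y = expression(R[eq] ~ "(RU)"),
      title = sprintf(
        "Langmuir isotherm: Kd = %.3g nM, Rmax = %.3g RU",
        object$Kd * 1e9, object$Rmax
      )
    )
}

#' Separate association / dissociation kinetic analysis
#'
#' Fits 1:1 Langmuir kinetics to a set of sensorgrams collected at several
#' analyte concentrations. Each dissociation phase is fit with a single
#' exponential decay `R = R0 * exp(-kd * t)` and the per-curve estimates
#' averaged into `kd`. Each association phase is fit with
#' `R = Req * (1 - exp(-kobs * t))`; the observed rates follow
#' `kobs = ka * [P] + kd`, so `ka` is the slope of the linear regression of
#' `kobs` on concentration (and the regression intercept is an independent
#' check on `kd`).
#'
#' @param sensorgrams a list of sensorgram tibbles, or one tibble holding
#'   several concentrations (grouped by `conc_M`). At least two distinct
#'   concentrations are required for `ka`; each dissociation phase needs at
#'   least 10 samples.
#'
#' @return a `kinetic_fit` object: `ka` (1/(M s)), `kd` (1/s, averaged over
#'   curves), `kobs_intercept` (regression intercept, 1/s), and `per_curve`
#'   (tibble of per-concentration `kobs` and dissociation-phase `kd`).
#' @examples
#' sgs <- lapply(c(1, 2, 4) * 100e-9, function(cc) {
#'   simulate_sensorgram(ka = 1e5, kd = 0.01, Rmax = 100, conc = cc)
#' })
#' fit_kinetics(sgs)
#' @export
fit_kinetics <- function(sensorgrams) {
  if (is.data.frame(sensorgrams)) {
    sensorgrams <- split(
      tibble::as_tibble(sensorgrams),
      sensorgrams$conc_M
    )
  }
  if (!is.list(sensorgrams) || length(sensorgrams) == 0) {
    abort("`sensorgrams` must be a (list of) sensorgram tibble(s).")
  }
  concs <- vapply(sensorgrams, function(s) s$conc_M[1], numeric(1))
  if (length(unique(concs)) < 2L) {
    abort("need sensorgrams at >= 2 distinct concentrations to estimate ka.")
  }

  per_curve <- purrr::map_dfr(sensorgrams, fit_one_curve)
  kd <- mean(per_curve$kd_curve, na.rm = TRUE)

  reg <- lm(kobs ~ conc_M, data = per_curve)
  ka <- unname(coef(reg)["conc_M"])
  intercept <- unname(coef(reg)["(Intercept)"])

  structure(
    list(
      ka = ka, kd = kd, kobs_intercept = intercept,
      per_curve = per_curve, kobs_regression = reg
    ),
    class = "kinetic_fit"
  )
}

# Single-exponential fits of one sensorgram's two phases.
fit_one_curve <- function(sg) {
  assoc <- sg[sg$phase == "association", ]
  diss <- sg[sg$phase == "dissociation", ]
  if (nrow(diss) < 10L) {
    abort("dissociation phase has fewer than 10 samples.")
  }
  conc <- sg$conc_M[1]

  # dissociation: R(t') = R0 * exp(-kd t'), t' from start of phase
  t0 <- max(assoc$time_s)
  td <- diss$time_s - t0
  r0_start <- max(diss$response_RU[1], 1e-9)
  pos <- diss$response_RU > 0
  kd_start <- if (sum(pos) >= 2) {
    max(-coef(lm(log(diss$response_RU[pos]) ~ td[pos]))[2], 1e-6)
  } else {
    0.01
  }
  fd <- tryCatch(
    minpack.lm::nlsLM(
      response_RU ~ R0 * exp(-kd * td),
      data = data.frame(response_RU = diss$response_RU, td = td),
      start = list(R0 = r0_start, kd = kd_start),
      lower = c(R0 = 0, kd = 1e-9),
      control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14, maxiter = 500)
    ),
    error = function(e) NULL
  )
  kd_curve <- if (is.null(fd)) NA_real_ else unname(coef(fd)["kd"])

  # association: R(t) = Req * (1 - exp(-kobs t))
  req_start <- max(assoc$response_RU)
  kobs_start <- {
    half <- assoc$time_s[which.min(abs(assoc$response_RU - req_start * 0.632))]
    if (half > 0) 1 / half else 0.1
  }
  fa <- tryCatch(
    minpack.lm::nlsLM(
      response_RU ~ Req * (1 - exp(-kobs * time_s)),
      data = assoc,
      start = list(Req = req_start, kobs = kobs_start),
      lower = c(Req = 0, kobs = 1e-9),
      control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14, maxiter = 500)
    ),
    error = function(e) NULL
  )
  kobs <- if (is.null(fa)) NA_real_ else unname(coef(fa)["kobs"])

  tibble::tibble(
    conc_M = conc,
    kobs = kobs,
    kd_curve = kd_curve,
    assoc_converged = !is.null(fa),
    dissoc_converged = !is.null(fd)
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> ka = %.4g 1/(M s), kd = %.4g 1/s (Kd = kd/ka = %.4g nM), %d curves\n",
    x$ka, x$kd, 1e9 * x$kd / x$ka, nrow(x$per_curve)
  ))
  invisible(x)
}

#' @rdname fit_kinetics
#' @param x,object a `kinetic_fit`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ka", "kd", "kobs_intercept"),
    estimate = c(x$ka, x$kd, x$kobs_intercept)
  )
}

#' @rdname fit_kinetics
#' @exportS3Method generics::glance
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    ka = x$ka, kd = x$kd, Kd_kinetic = x$kd / x$ka,
    kobs_intercept = x$kobs_intercept,
    n_curves = nrow(x$per_curve),
    r.squared = summary(x$kobs_regression)$r.squared
  )
}

#' @rdname fit_kinetics
#' @exportS3Method ggplot2::autoplot
autoplot.kinetic_fit <- function(object, ...) {
  ggplot2::ggplot(object$per_curve, ggplot2::aes(.data$conc_M, .data$kobs)) +
    ggplot2::geom_abline(
      intercept = object$kobs_intercept, slope = object$ka,
      colour = "steelblue"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "[P] (M)", y = expression(k[obs] ~ (s^-1)),
      title = sprintf(
        "kobs = ka[P] + kd: ka = %.3g 1/(M s), kd = %.3g 1/s",
        object$ka, object$kd
      )
    )
}
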