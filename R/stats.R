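#' Per-group mean, SEM and n
#'
#' Summarises a tidy long table of measurements into the per-group
#' mean +/- SEM (standard error of the mean, `sd / sqrt(n)`) used for
#' figure bars. Groups with a single observation get `NA` SEM and are
#' flagged.
#'
#' @param data tidy data frame with one row per measurement.
#' @param value unquoted column of measurements.
#' @param group unquoted grouping column.
#'
#' @return a tibble with `group`, `n`, `mean`, `sem`, `sem_defined`.
#' @examples
#' df <- data.frame(group = rep(c("WT", "K85A"), each = 3),
#'                  value = c(98, 102, 100, 55, 60, 50))
#' summarize_groups(df, value, group)
#' @export
summarize_groups <- function(data, value, group) {
  data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sem = ifelse(dplyr::n() >= 2, sd({{ value }}) / sqrt(dplyr::n()), NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(sem_defined = !is.na(.data$sem))
}

#' One-way ANOVA with reference-group flags
#'
#' Classical one-way analysis of variance across groups, plus per-group
#' significance flags from pairwise Welch t-tests against a reference
#' group (typically wild type) at a stated alpha. No multiplicity
#' correction is applied by default, matching the common single-threshold
#' reporting style; `p_adjust = "bonferroni"` is available.
#'
#' @param data tidy data frame, one row per measurement.
#' @param value,group unquoted measurement and grouping columns.
#' @param reference reference group label; default the first group level
#'   (or `"WT"` if present).
#' @param alpha significance threshold for the flags.
#' @param p_adjust `"none"` (default) or `"bonferroni"` for the pairwise
#'   p-values.
#'
#' @return a `pm_anova` object; `glance()` gives the omnibus F test
#'   (`statistic`, `df`, `df.residual`, `p.value`, `degenerate`), `tidy()`
#'   the pairwise comparisons (`group`, `estimate`, `p.value`,
#'   `significant`). Zero within-group variance with equal means is
#'   degenerate: F is reported as 0 with `degenerate = TRUE`.
#' @examples
#' df <- data.frame(group = rep(c("WT", "K85A", "K84/85A"), each = 4),
#'                  value = c(rnorm(4, 100, 5), rnorm(4, 60, 5), rnorm(4, 30, 5)))
#' glance(anova_oneway(df, value, group, reference = "WT", alpha = 0.01))
#' @export
anova_oneway <- function(data, value, group, reference = NULL,
                         alpha = 0.05, p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  df <- dplyr::tibble(
    value = dplyr::pull(data, {{ value }}),
    group = as.character(dplyr::pull(data, {{ group }}))
  )
  counts <- table(df$group)
  if (length(counts) < 2L) abort("need >= 2 groups for ANOVA.")
  if (any(counts < 2L)) abort("each group needs n >= 2.")

  k <- length(counts)
  n <- nrow(df)
  grand <- mean(df$value)
  means <- tapply(df$value, df$group, mean)
  ssb <- sum(counts * (means - grand)^2)
  ssw <- sum((df$value - means[df$group])^2)
  df1 <- k - 1
  df2 <- n - k

  degenerate <- FALSE
  if (ssw <= .Machine$double.eps * max(1, sum(df$value^2))) {
    degenerate <- TRUE
    if (ssb <= .Machine$double.eps * max(1, sum(df$value^2))) {
      f_stat <- 0
      p <- 1
    } else {
      f_stat <- Inf
      p <- 0
    }
  } else {
    f_stat <- (ssb / df1) / (ssw / df2)
    p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  }

  reference <- reference %||%
    (if ("WT" %in% names(counts)) "WT" else names(counts)[1])
  if (!reference %in% names(counts)) {
    abort(sprintf("reference group '%s' not in data.", reference))
  }
  others <- setdiff(names(counts), reference)
  comp <- purrr::map_dfr(others, function(g) {
    tt <- tryCatch(
      stats::t.test(df$value[df$group == g], df$value[df$group == reference]),
      error = function(e) NULL
    )
    tibble::tibble(
      group = g,
      estimate = means[[g]] - means[[reference]],
      p.value = if (is.null(tt)) NA_real_ else tt$p.value
    )
  })
  if (p_adjust == "bonferroni") {
    comp$p.value <- stats::p.adjust(comp$p.value, method = "bonferroni")
  }
  comp$significant <- !is.na(comp$p.value) & comp$p.value < alpha

  structure(
    list(
      omnibus = tibble::tibble(
        statistic = f_stat, df = df1, df.residual = df2,
        p.value = p, degenerate = degenerate
      ),
      comparisons = comp,
      reference = reference, alpha = alpha
    ),
    class = "pm_anova"
  )
}

#' @export
print.pm_anova <- function(x, ...) {
  o <- x$omnibus
  cat(sprintf(
    "<pm_anova> one-way: F(%d, %d) = %.4g, p = %.3g%s; reference '%s', alpha %.3g\n",
    o$df, o$df.residual, o$statistic, o$p.value,
    if (o$degenerate) " [degenerate]" else "", x$reference, x$alpha
  ))
  print(x$comparisons)
  invisible(x)
}

#' @rdname anova_oneway
#' @param x an object returned by [anova_oneway()].
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.pm_anova <- function(x, ...) x$comparisons

#' @rdname anova_oneway
#' @exportS3Method generics::glance
glance.pm_anova <- function(x, ...) x$omnibus

#' Two-way ANOVA with interaction
#'
#' Classical two-factor analysis of variance (main effects and
#' interaction) on a balanced or near-balanced design, as used when two
#' co-expressed constructs are scored across mutant backgrounds. Every
#' factor-level combination must be observed; a missing cell is an error
#' naming the cell.
#'
#' @param data tidy data frame, one row per measurement.
#' @param value,factor1,factor2 unquoted measurement and factor columns.
#' @param alpha significance threshold for the flags.
#'
#' @return a tibble with one row per term (`factor1`, `factor2`,
#'   `interaction`): `df`, `sumsq`, `statistic`, `p.value`, `significant`.
#'   With zero residual variance, terms with zero sum of squares report
#'   F = 0 (p = 1) and others F = Inf (p = 0).
#' @export
anova_twoway <- function(data, value, factor1, factor2, alpha = 0.05) {
  df <- dplyr::tibble(
    value = dplyr::pull(data, {{ value }}),
    a = factor(dplyr::pull(data, {{ factor1 }})),
    b = factor(dplyr::pull(data, {{ factor2 }}))
  )
  cells <- table(df$a, df$b)
  if (any(cells == 0)) {
    miss <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "missing cell: no observations for %s = '%s', %s = '%s'.",
      rlang::as_name(rlang::enquo(factor1)), rownames(cells)[miss[1]],
      rlang::as_name(rlang::enquo(factor2)), colnames(cells)[miss[2]]
    ))
  }

  fit <- stats::aov(value ~ a * b, data = df)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  res_i <- terms == "Residuals"
  ss <- tab[["Sum Sq"]]
  dfree <- tab[["Df"]]
  ss_res <- ss[res_i]
  df_res <- dfree[res_i]

  eff <- which(!res_i)
  scale <- .Machine$double.eps * max(1, sum(df$value^2))
  out <- purrr::map_dfr(eff, function(i) {
    if (ss_res <= scale) {
      if (ss[i] <= scale) {
        f <- 0
        p <- 1
      } else {
        f <- Inf
        p <- 0
      }
    } else {
      f <- (ss[i] / dfree[i]) / (ss_res / df_res)
      p <- pf(f, dfree[i], df_res, lower.tail = FALSE)
    }
    tibble::tibble(
      term = c(a = "factor1", b = "factor2", `a:b` = "interaction")[[terms[i]]],
      df = dfree[i], sumsq = ss[i], statistic = f, p.value = p
    )
  })
  out$significant <- out$p.value < alpha
  out
}
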