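test_that("group summaries report mean, SEM and flag singletons", {
  df <- tibble::tibble(
    group = c("a", "a", "a", "b", "b", "c"),
    value = c(4, 4, 4, 1, 3, 9)
  )
  s <- summarize_groups(df, value, group)
  expect_equal(s$mean[s$group == "a"], 4)
  expect_equal(s$sem[s$group == "a"], 0)
  expect_equal(s$mean[s$group == "b"], 2)
  expect_equal(s$sem[s$group == "b"], 1) # sd sqrt(2) / sqrt(2)
  expect_true(is.na(s$sem[s$group == "c"]))
  expect_false(s$sem_defined[s$group == "c"])
})

test_that("one-way ANOVA matches the textbook sums-of-squares oracle", {
  df <- tibble::tibble(
    group = rep(c("WT", "m1", "m2"), times = c(4, 3, 5)),
    value = c(10, 12, 11, 9, 7, 6, 8, 15, 14, 16, 13, 17)
  )
  res <- glance(anova_oneway(df, value, group))

  # oracle: explicit between/within sums of squares
  grand <- mean(df$value)
  means <- tapply(df$value, df$group, mean)
  ns <- table(df$group)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((df$value - means[df$group])^2)
  f_oracle <- (ssb / 2) / (ssw / 9)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(res$p.value, pf(f_oracle, 2, 9, lower.tail = FALSE))
  expect_false(res$degenerate)
})

test_that("one-way ANOVA handles degenerate and fully separated data", {
  flat <- tibble::tibble(group = rep(c("a", "b"), each = 3), value = 5)
  res <- glance(anova_oneway(flat, value, group))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_true(res$degenerate)

  sep <- tibble::tibble(
    group = rep(c("a", "b"), each = 3),
    value = c(0, 0, 0, 10, 10, 10) + c(1e-4, -1e-4, 0, 1e-4, -1e-4, 0)
  )
  res2 <- glance(anova_oneway(sep, value, group))
  expect_lt(res2$p.value, 1e-8)
})

test_that("reference-group flags use Welch tests at the stated alpha", {
  set.seed(1)
  df <- tibble::tibble(
    group = rep(c("WT", "strong", "null"), each = 6),
    value = c(rnorm(6, 100, 3), rnorm(6, 40, 3), rnorm(6, 100, 3))
  )
  res <- anova_oneway(df, value, group, reference = "WT", alpha = 0.01)
  comp <- tidy(res)
  expect_true(comp$significant[comp$group == "strong"])
  expect_false(comp$significant[comp$group == "null"])
  # Welch oracle
  w <- t.test(df$value[df$group == "strong"], df$value[df$group == "WT"])
  expect_equal(comp$p.value[comp$group == "strong"], w$p.value)

  bonf <- anova_oneway(df, value, group,
    reference = "WT", alpha = 0.01, p_adjust = "bonferroni"
  )
  expect_equal(
    tidy(bonf)$p.value,
    pmin(comp$p.value * 2, 1),
    tolerance = 1e-12
  )
})

test_that("ANOVA F is invariant under shift and scale of the data", {
  set.seed(2)
  df <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 5),
    value = rnorm(15, rep(c(5, 7, 6), each = 5))
  )
  f0 <- glance(anova_oneway(df, value, group))$statistic
  shifted <- dplyr::mutate(df, value = value + 123)
  scaled <- dplyr::mutate(df, value = value * 42)
  expect_equal(glance(anova_oneway(shifted, value, group))$statistic, f0)
  expect_equal(glance(anova_oneway(scaled, value, group))$statistic, f0)
})

test_that("the F-test p-value agrees with a permutation estimate", {
  set.seed(3)
  df <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 8),
    value = rnorm(24, rep(c(0, 0.8, 0.4), each = 8))
  )
  p_f <- glance(anova_oneway(df, value, group))$p.value

  f_of <- function(values) {
    means <- tapply(values, df$group, mean)
    ns <- table(df$group)
    ssb <- sum(ns * (means - mean(values))^2)
    ssw <- sum((values - means[df$group])^2)
    (ssb / 2) / (ssw / 21)
  }
  f_obs <- f_of(df$value)
  n_perm <- 10000
  exceed <- vapply(seq_len(n_perm), function(i) {
    f_of(sample(df$value)) >= f_obs
  }, logical(1))
  p_perm <- mean(exceed)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / n_perm)
  expect_lt(abs(p_f - p_perm), mc_err + 0.01)
})

test_that("two-way ANOVA matches the balanced sums-of-squares oracle", {
  set.seed(4)
  df <- tidyr::expand_grid(
    a = c("WT", "mut"), b = c("x", "y"), rep = 1:4
  )
  df$value <- rnorm(16, 10) + (df$a == "mut") * 3 + (df$b == "y") * 1.5 +
    (df$a == "mut" & df$b == "y") * 0.8
  res <- anova_twoway(df, value, a, b)

  # oracle: balanced two-factor sums of squares
  gm <- mean(df$value)
  am <- tapply(df$value, df$a, mean)
  bm <- tapply(df$value, df$b, mean)
  cm <- tapply(df$value, interaction(df$a, df$b), mean)
  ssa <- 8 * sum((am - gm)^2)
  ssb <- 8 * sum((bm - gm)^2)
  sscell <- 4 * sum((cm - gm)^2)
  ssab <- sscell - ssa - ssb
  sse <- sum((df$value - cm[interaction(df$a, df$b)])^2)
  expect_equal(res$sumsq[res$term == "factor1"], ssa, tolerance = 1e-9)
  expect_equal(res$sumsq[res$term == "factor2"], ssb, tolerance = 1e-9)
  expect_equal(res$sumsq[res$term == "interaction"], ssab, tolerance = 1e-9)
  f_a <- (ssa / 1) / (sse / 12)
  expect_equal(res$statistic[res$term == "factor1"], f_a, tolerance = 1e-9)
})

test_that("two-way ANOVA flags degenerate designs correctly", {
  flat <- tidyr::expand_grid(a = c("p", "q"), b = c("u", "v"), rep = 1:3)
  flat$value <- 2
  res <- anova_twoway(flat, value, a, b)
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p.value == 1))

  # additive, noiseless: interaction exactly zero, main effects saturated
  add <- tidyr::expand_grid(a = c("p", "q"), b = c("u", "v"), rep = 1:3)
  add$value <- 1 + (add$a == "q") * 2 + (add$b == "v") * 5
  res2 <- anova_twoway(add, value, a, b)
  expect_equal(res2$statistic[res2$term == "interaction"], 0)
  expect_true(all(res2$statistic[res2$term != "interaction"] == Inf))

  miss <- tibble::tibble(
    a = c("p", "p", "q"), b = c("u", "v", "u"), value = 1:3
  )
  expect_error(anova_twoway(miss, value, a, b), "missing cell")
})
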