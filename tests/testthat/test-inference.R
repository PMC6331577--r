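make_lmm_data <- function(n = 120, sigma_year = 0.3, seed = 1) {
  set.seed(seed)
  yr <- sample(2005:2011, n, replace = TRUE)
  u <- stats::rnorm(7, 0, sigma_year)
  names(u) <- as.character(2005:2011)
  x <- stats::runif(n)
  z <- stats::rnorm(n)
  y <- 1 + 2 * x + u[as.character(yr)] + stats::rnorm(n, 0, 0.5)
  data.frame(y = y, x = x, z = z, brood_year = yr)
}

test_that("with no group variance the mixed fit collapses to least squares", {
  d <- make_lmm_data(sigma_year = 0, seed = 2)
  fit <- fit_lmm(y ~ x, d)
  ols <- stats::lm(y ~ x, data = d)
  expect_equal(coef(fit), stats::coef(ols), tolerance = 1e-6)
  expect_equal(fit$sigma_group, 0, tolerance = 1e-4)
})

test_that("null data yields slope estimates within 3 SE of zero", {
  set.seed(8)
  d <- make_lmm_data(seed = 8)
  d$y <- stats::rnorm(nrow(d))
  fit <- fit_lmm(y ~ x + z, d)
  tab <- fit$coefficients
  for (term in c("x", "z"))
    expect_lt(abs(tab$estimate[tab$term == term] / tab$se[tab$term == term]), 3)
})

test_that("the AIC identity holds and duplicate candidates tie at zero", {
  d <- make_lmm_data(seed = 3)
  fit <- fit_lmm(y ~ x, d)
  expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$npar)
  expect_equal(AIC(fit), fit$AIC)
  lad <- select_by_aic(list(a = y ~ x, b = y ~ x), d)
  expect_equal(lad$table$dAIC, c(0, 0))
  fixed <- fit_lmm(y ~ x, d, method = "fixed")
  expect_equal(fixed$AIC, -2 * fixed$logLik + 2 * fixed$npar)
})

test_that("model selection prefers the generating structure", {
  # the extra term is the generating log-egg effect at its default magnitude:
  # the fuller model should win nearly always
  wins <- 0; reps <- 60
  for (i in 1:reps) {
    s <- simulate_crosses(n_pairs = 85, seed = 4000 + i)
    fam <- truth_family_table(s)
    fam$log_count <- log(fam$n_offspring)
    fam$log_eggs <- log(fam$egg_number)
    lad <- select_by_aic(list(
      base = log_count ~ dam_background + dam_background:pair_introgression,
      eggs = log_count ~ dam_background + dam_background:pair_introgression + log_eggs),
      fam)
    if (lad$table$model[1] == "eggs") wins <- wins + 1
  }
  expect_gte(wins / reps, 0.9)
})

test_that("rank-deficient designs are rejected with the aliased terms named", {
  d <- make_lmm_data(seed = 5)
  d$x2 <- d$x
  expect_error(fit_lmm(y ~ x + x2, d), "x2")
  expect_error(fit_lmm(y ~ x + x2, d, method = "fixed"), "x2")
  expect_error(fit_lmm(y ~ nope, d), "nope")
})

test_that("a single grouping level degrades to a fixed-effects fit with warning", {
  d <- make_lmm_data(seed = 6)
  d$brood_year <- 2005
  expect_warning(fit <- fit_lmm(y ~ x, d), "fewer than 2 grouping levels")
  expect_false(fit$mixed)
})

test_that("Wald transformation reproduces the reporting-scale intervals", {
  ci <- wald_ci_transform(1.5145, 0.6667, "exp")
  expect_equal(round(unname(ci), 2), c(4.55, 1.23, 16.80))
  ci2 <- wald_ci_transform(1.72152, 0.75118, "exp")
  expect_equal(round(unname(ci2), 2), c(5.59, 1.28, 24.38))
  z <- wald_ci_transform(0.7, 0, "exp")
  expect_equal(unname(z), rep(exp(0.7), 3))
  pct <- wald_ci_transform(log(1.062), 0.019, "percent")
  expect_lt(pct[["lower"]], pct[["point"]])
  expect_lt(pct[["point"]], pct[["upper"]])
  expect_equal(pct[["point"]], 6.2, tolerance = 1e-10)
  expect_error(wald_ci_transform(1, -0.1), "se")
  expect_error(wald_ci_transform(1, 0.1, "sqrt"))
})

test_that("the smolt model collapses correctly for a single sea-age class", {
  a <- growth_table(simulate_adults(n = 400, origin = "hatchery", seed = 9))
  a$sea_age <- "2"
  fit <- fit_smolt_length_model(a)
  pooled <- fit_lmm(log(smolt_length) ~ introgression, a)
  expect_equal(coef(fit), coef(pooled))
  expect_named(fit$percent_effect, c("point", "lower", "upper"))
})

test_that("egg models return the two reported specifications", {
  s <- simulate_crosses(n_pairs = 200, seed = 77)
  em <- fit_egg_models(truth_dam_table(s))
  expect_true(all(c("dam_backgroundhatchery", "dam_backgroundwild:introgression") %in%
                    em$size$coefficients$term))
  expect_false("introgression" %in% em$number$coefficients$term)
  expect_equal(em$size$AIC, -2 * em$size$logLik + 2 * em$size$npar)
})
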