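test_that("the fixed-effects limit matches an independent multinomial fit", {
  skip_if_not_installed("nnet")
  a <- growth_table(simulate_adults(n = 600, origin = "hatchery", seed = 7))
  fit <- fit_sea_age_model(a, include_d = FALSE, random = FALSE)
  oracle <- nnet::multinom(factor(sea_age, levels = c("3+", "1", "2")) ~ introgression,
                           data = a, trace = FALSE, reltol = 1e-12)
  expect_equal(fit$logLik, as.numeric(stats::logLik(oracle)), tolerance = 1e-3)
  oc <- stats::coef(oracle)
  expect_equal(unname(fit$coefficients[c("a1", "a2")]), unname(oc[, 1]),
               tolerance = 1e-3)
  expect_equal(unname(fit$coefficients[c("b1", "b2")]), unname(oc[, 2]),
               tolerance = 1e-3)
})

test_that("implied category probabilities always sum to one", {
  a <- growth_table(simulate_adults(n = 500, origin = "hatchery", seed = 3))
  fit <- fit_sea_age_model(a)
  pr <- predict(fit, introgression = seq(-0.2, 1.2, 0.1), dev = 0.05)
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)))
  expect_true(all(pr > 0))
})

test_that("a symmetric baseline gives zero intercepts", {
  d <- data.frame(sea_age = rep(c("1", "2", "3+"), each = 30),
                  introgression = 0.2,
                  birth_year = rep(2001:2003, 30))
  fit <- fit_sea_age_model(d, include_b = FALSE, include_d = FALSE, random = FALSE)
  expect_equal(unname(fit$coefficients[["a1"]]), 0, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients[["a2"]]), 0, tolerance = 1e-4)
})

test_that("an absent sea-age category is rejected with a clear message", {
  d <- data.frame(sea_age = rep(c("1", "2"), 20), introgression = 0.1,
                  birth_year = 2001)
  expect_error(fit_sea_age_model(d), "absent")
})

test_that("the Laplace likelihood matches Gauss-Hermite quadrature", {
  a <- growth_table(simulate_adults(n = 300, origin = "hatchery",
                                    years = 2001:2005, seed = 13))
  fit <- fit_sea_age_model(a, include_d = FALSE)
  # independent quadrature oracle for the marginal likelihood at the optimum
  gh <- gauss_hermite(25)
  cf <- fit$coefficients; s <- fit$sigma_t
  y <- as.character(a$sea_age)
  y1 <- as.numeric(y == "1"); y2 <- as.numeric(y == "2")
  ll_quad <- 0
  for (j in sort(unique(a$birth_year))) {
    k <- a$birth_year == j
    e1 <- cf[["a1"]] + cf[["b1"]] * a$introgression[k]
    e2 <- cf[["a2"]] + cf[["b2"]] * a$introgression[k]
    f <- outer(gh$nodes * sqrt(2) * s[1], gh$nodes * sqrt(2) * s[2],
               Vectorize(function(t1, t2) {
                 den <- 1 + exp(e1 + t1) + exp(e2 + t2)
                 exp(sum(y1[k] * (e1 + t1) + y2[k] * (e2 + t2) - log(den)))
               }))
    ll_quad <- ll_quad + log(sum(outer(gh$weights, gh$weights) * f) / pi)
  }
  expect_equal(fit$logLik, ll_quad, tolerance = 1e-3)
})

test_that("the introgression likelihood-ratio test is a 2-df chi-squared test", {
  a <- growth_table(simulate_adults(n = 400, origin = "hatchery", seed = 19))
  lr <- sea_age_lrt(a, include_d = FALSE)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$df, 2)
  expect_equal(lr$p_value,
               stats::pchisq(lr$statistic, 2, lower.tail = FALSE))
  expect_equal(lr$full$npar - lr$reduced$npar, 2)
})
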