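## Multinomial (logit) mixed model for sea age with categories {1, 2, 3+}:
## two log-odds contrasts against the 3+ baseline, each with an intercept, a
## within-year slope on individual ancestry D, a slope on the year-mean
## deviation (Dbar_j - Dgrand), and an independent normal year random effect.
## The marginal likelihood integrates the two year-level effects by a Laplace
## approximation with an inner Newton solve per year.

## joint log-density of one year's data and random effects t = (t1, t2)
seaage_year_g <- function(t, eta1f, eta2f, y1, y2, s1, s2) {
  e1 <- eta1f + t[1]; e2 <- eta2f + t[2]
  m <- pmax(e1, pmax(e2, 0))
  lden <- m + log(exp(-m) + exp(e1 - m) + exp(e2 - m))
  sum(y1 * e1 + y2 * e2 - lden) -
    t[1]^2 / (2 * s1^2) - t[2]^2 / (2 * s2^2) - log(2 * pi * s1 * s2)
}

seaage_year_laplace <- function(eta1f, eta2f, y1, y2, s1, s2) {
  t <- c(0, 0)
  for (it in 1:50) {
    e1 <- eta1f + t[1]; e2 <- eta2f + t[2]
    d <- 1 + exp(e1) + exp(e2)
    p1 <- exp(e1) / d; p2 <- exp(e2) / d
    gr <- c(sum(y1 - p1) - t[1] / s1^2, sum(y2 - p2) - t[2] / s2^2)
    h11 <- sum(p1 * (1 - p1)) + 1 / s1^2
    h22 <- sum(p2 * (1 - p2)) + 1 / s2^2
    h12 <- -sum(p1 * p2)
    det <- h11 * h22 - h12^2
    step <- c(h22 * gr[1] - h12 * gr[2], -h12 * gr[1] + h11 * gr[2]) / det
    t <- t + step
    if (max(abs(gr)) < 1e-10) break
  }
  e1 <- eta1f + t[1]; e2 <- eta2f + t[2]
  d <- 1 + exp(e1) + exp(e2)
  p1 <- exp(e1) / d; p2 <- exp(e2) / d
  h11 <- sum(p1 * (1 - p1)) + 1 / s1^2
  h22 <- sum(p2 * (1 - p2)) + 1 / s2^2
  h12 <- -sum(p1 * p2)
  ldet <- log(h11 * h22 - h12^2)
  list(ll = seaage_year_g(t, eta1f, eta2f, y1, y2, s1, s2) + log(2 * pi) - ldet / 2,
       t = t)
}

#' Fit the multinomial-logit mixed model for sea age
#'
#' Sea age (1, 2, 3+ winters at sea) is modelled through two log-odds
#' contrasts against the 3+ baseline. Each contrast has an intercept, a
#' within-year slope on individual proportion farmed ancestry, a slope on the
#' deviation of the birth-year mean ancestry from the grand mean (separating
#' within- from among-year effects), and a normal year random effect; the two
#' contrasts' random effects are independent. The marginal likelihood
#' integrates the year effects by a Laplace approximation (inner Newton solve
#' per year) and is maximized numerically. Set `random = FALSE` for the plain
#' fixed-effects multinomial logit, `include_b`/`include_d` to drop the
#' ancestry or year-deviation terms.
#'
#' @param data data frame with `sea_age` (values "1", "2", "3+"),
#'   `introgression` and `birth_year`; filtered by `sex` first when both a
#'   `sex` column and the `sex` argument are given.
#' @param sex optional "F" or "M".
#' @param include_b include the within-year ancestry slopes b1, b2?
#' @param include_d include the year-deviation slopes d1, d2?
#' @param random include the year random effects?
#' @return An object of class `seaage_fit` with `coefficients` (a1, a2, b1,
#'   b2, d1, d2 as applicable), `sigma_t` (the two random-effect SDs),
#'   `logLik`, `AIC`, `npar`, `converged`.
#' @export
fit_sea_age_model <- function(data, sex = NULL, include_b = TRUE,
                              include_d = TRUE, random = TRUE) {
  if (!is.null(sex) && "sex" %in% names(data)) data <- data[data$sex == sex, ]
  need <- c("sea_age", "introgression", "birth_year")
  absent <- setdiff(need, names(data))
  stop_if(length(absent) > 0, "data lacks: ", paste(absent, collapse = ", "))
  y <- as.character(data$sea_age)
  stop_if(!all(y %in% c("1", "2", "3+")), "sea_age must be one of '1', '2', '3+'")
  for (lv in c("1", "2", "3+"))
    stop_if(!any(y == lv), sprintf("sea-age category '%s' absent from the data", lv))
  D <- data$introgression
  year <- as.character(data$birth_year)
  yrs <- sort(unique(year))
  dbar <- tapply(D, year, mean)
  dgrand <- mean(dbar)
  cdev <- dbar - dgrand
  y1 <- as.numeric(y == "1"); y2 <- as.numeric(y == "2")

  par_names <- c("a1", "a2",
                 if (include_b) c("b1", "b2"),
                 if (include_d) c("d1", "d2"),
                 if (random) c("log_s1", "log_s2"))
  unpack <- function(th) {
    i <- 2
    b <- c(0, 0); d <- c(0, 0); s <- c(1e-8, 1e-8)
    a <- th[1:2]
    if (include_b) { b <- th[i + 1:2]; i <- i + 2 }
    if (include_d) { d <- th[i + 1:2]; i <- i + 2 }
    if (random) s <- exp(th[i + 1:2])
    list(a = a, b = b, d = d, s = s)
  }
  negll <- function(th) {
    p <- unpack(th)
    tot <- 0
    for (j in yrs) {
      k <- year == j
      eta1f <- p$a[1] + p$b[1] * D[k] + p$d[1] * cdev[[j]]
      eta2f <- p$a[2] + p$b[2] * D[k] + p$d[2] * cdev[[j]]
      if (random) {
        tot <- tot + seaage_year_laplace(eta1f, eta2f, y1[k], y2[k],
                                         p$s[1], p$s[2])$ll
      } else {
        m <- pmax(eta1f, pmax(eta2f, 0))
        lden <- m + log(exp(-m) + exp(eta1f - m) + exp(eta2f - m))
        tot <- tot + sum(y1[k] * eta1f + y2[k] * eta2f - lden)
      }
    }
    -tot
  }
  n1 <- sum(y1); n2 <- sum(y2); n3 <- length(y) - n1 - n2
  start <- c(log(n1 / n3), log(n2 / n3),
             if (include_b) c(0, 0), if (include_d) c(0, 0),
             if (random) c(log(0.3), log(0.3)))
  lower <- rep(-Inf, length(start)); upper <- rep(Inf, length(start))
  if (random) {
    lower[length(start) - 1:0] <- -5
    upper[length(start) - 1:0] <- 2
  }
  opt <- stats::nlminb(start, negll, lower = lower, upper = upper,
                       control = list(iter.max = 500, eval.max = 1000))
  p <- unpack(opt$par)
  est <- stats::setNames(opt$par, par_names)
  coefs <- c(a1 = p$a[1], a2 = p$a[2])
  if (include_b) coefs <- c(coefs, b1 = p$b[1], b2 = p$b[2])
  if (include_d) coefs <- c(coefs, d1 = p$d[1], d2 = p$d[2])
  npar <- length(start)
  out <- list(coefficients = coefs,
              sigma_t = if (random) stats::setNames(p$s, c("t1", "t2")) else c(t1 = 0, t2 = 0),
              logLik = -opt$objective, npar = npar,
              AIC = 2 * opt$objective + 2 * npar,
              converged = opt$convergence == 0,
              include_b = include_b, include_d = include_d, random = random,
              n = length(y), n_years = length(yrs),
              dgrand = dgrand, par = est)
  class(out) <- "seaage_fit"
  out
}

#' @export
print.seaage_fit <- function(x, ...) {
  cat(sprintf("Multinomial-logit sea-age model (%s), n = %d, %d years\n",
              if (x$random) "Laplace-integrated year effects" else "fixed effects",
              x$n, x$n_years))
  print(round(x$coefficients, 4))
  if (x$random) cat(sprintf("  sigma_t: %.4f / %.4f\n", x$sigma_t[1], x$sigma_t[2]))
  cat(sprintf("  logLik = %.3f, AIC = %.2f%s\n", x$logLik, x$AIC,
              if (x$converged) "" else "  [convergence flagged]"))
  invisible(x)
}

#' @export
logLik.seaage_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n, class = "logLik")
}

#' Implied sea-age category probabilities
#'
#' Probabilities of sea age 1, 2 and 3+ at given ancestry values, with year
#' effects at zero and the year-mean deviation at `dev`.
#'
#' @param object a `seaage_fit`.
#' @param introgression numeric vector of ancestry values.
#' @param dev year-mean ancestry deviation from the grand mean (default 0).
#' @param ... unused.
#' @return matrix with columns `"1"`, `"2"`, `"3+"`, rows summing to one.
#' @export
predict.seaage_fit <- function(object, introgression = 0, dev = 0, ...) {
  cf <- object$coefficients
  b1 <- if (object$include_b) cf[["b1"]] else 0
  b2 <- if (object$include_b) cf[["b2"]] else 0
  d1 <- if (object$include_d) cf[["d1"]] else 0
  d2 <- if (object$include_d) cf[["d2"]] else 0
  e1 <- cf[["a1"]] + b1 * introgression + d1 * dev
  e2 <- cf[["a2"]] + b2 * introgression + d2 * dev
  den <- 1 + exp(e1) + exp(e2)
  cbind("1" = exp(e1) / den, "2" = exp(e2) / den, "3+" = 1 / den)
}

#' Likelihood-ratio test for an ancestry effect on sea age
#'
#' Fits the sea-age model with and without the within-year ancestry slopes
#' (b1 = b2 = 0 in the reduced model) and compares twice the log-likelihood
#' difference to a chi-squared distribution with 2 degrees of freedom.
#'
#' @param data,sex,include_d,random as in [fit_sea_age_model()].
#' @return list with `full`, `reduced`, `statistic`, `df`, `p_value`.
#' @export
sea_age_lrt <- function(data, sex = NULL, include_d = TRUE, random = TRUE) {
  full <- fit_sea_age_model(data, sex = sex, include_b = TRUE,
                            include_d = include_d, random = random)
  reduced <- fit_sea_age_model(data, sex = sex, include_b = FALSE,
                               include_d = include_d, random = random)
  stat <- max(0, 2 * (full$logLik - reduced$logLik))
  list(full = full, reduced = reduced, statistic = stat, df = 2,
       p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}
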