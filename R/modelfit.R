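#' Fit a linear mixed model with one random intercept by maximum likelihood
#'
#' The workhorse behind the study's log-count and log-phenotype models: a
#' Gaussian linear mixed model with a single random intercept (brood year or
#' run year), estimated by full maximum likelihood (not REML) so that AIC
#' comparisons across fixed-effect structures are coherent. With fewer than
#' two grouping levels, or with `method = "fixed"`, the model degrades to an
#' ordinary least-squares fit (with a warning in the former case).
#'
#' @param fixed fixed-effects formula, e.g. `log(n_offspring) ~ dam_background
#'   + dam_background:pair_introgression`.
#' @param data data frame.
#' @param random name of the grouping column for the random intercept
#'   (default `"brood_year"`), or `NULL` for a fixed-effects fit.
#' @param method `"mixed"` (default) or `"fixed"` (ordinary least squares; the
#'   least-squares variant of the same models).
#' @return An object of class `stock_fit` with coefficient table, variance
#'   components, log-likelihood, AIC, and the underlying fit.
#' @export
fit_lmm <- function(fixed, data, random = "brood_year",
                    method = c("mixed", "fixed")) {
  method <- match.arg(method)
  stopifnot(inherits(fixed, "formula"))
  vars <- all.vars(fixed)
  absent <- setdiff(vars, names(data))
  stop_if(length(absent) > 0, "variables not in data: ", paste(absent, collapse = ", "))
  mixed <- method == "mixed" && !is.null(random)
  if (mixed) {
    stop_if(!random %in% names(data), "grouping variable '", random, "' not in data")
    if (length(unique(data[[random]])) < 2) {
      warning("fewer than 2 grouping levels; falling back to a fixed-effects fit")
      mixed <- FALSE
    }
  }
  if (mixed) {
    form <- stats::as.formula(paste(deparse(fixed, width.cutoff = 500),
                                    sprintf("+ (1 | %s)", random)))
    fit <- lme4::lmer(form, data = data, REML = FALSE,
                      control = lme4::lmerControl(check.conv.singular = "ignore",
                                                  calc.derivs = FALSE))
    ## rank deficiency: lmer silently drops aliased columns; reject instead
    X <- stats::model.matrix(fixed, data)
    aliased <- setdiff(colnames(X), names(lme4::fixef(fit)))
    stop_if(length(aliased) > 0,
            "rank-deficient design; aliased terms: ", paste(aliased, collapse = ", "))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_group <- vc$sdcor[vc$grp == random][1]
    sigma_resid <- stats::sigma(fit)
    ll <- stats::logLik(fit)
    conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  } else {
    fit <- stats::lm(fixed, data = data)
    stop_if(any(is.na(stats::coef(fit))),
            "rank-deficient design; aliased terms: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    sigma_group <- NA_real_
    sigma_resid <- sqrt(sum(stats::residuals(fit)^2) / stats::nobs(fit))  # ML sigma
    ll <- stats::logLik(fit)
    conv <- TRUE
  }
  npar <- attr(ll, "df")
  out <- list(
    call = match.call(), fixed = fixed, random = if (mixed) random else NULL,
    mixed = mixed, fit = fit,
    coefficients = data.frame(term = names(beta), estimate = as.numeric(beta),
                              se = as.numeric(se), stringsAsFactors = FALSE),
    sigma_group = sigma_group, sigma_resid = sigma_resid,
    logLik = as.numeric(ll), npar = npar,
    AIC = -2 * as.numeric(ll) + 2 * npar,
    n = stats::nobs(fit), converged = conv)
  class(out) <- "stock_fit"
  out
}

#' @export
print.stock_fit <- function(x, digits = 4, ...) {
  cat(if (x$mixed) sprintf("Linear mixed model (ML), random intercept: %s\n", x$random)
      else "Linear model (least squares)\n")
  cat("  ", deparse(x$fixed, width.cutoff = 500), "\n", sep = "")
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, digits); tab$se <- signif(tab$se, digits)
  print(tab, row.names = FALSE)
  if (x$mixed)
    cat(sprintf("  sigma(%s) = %.4f, sigma(resid) = %.4f\n",
                x$random, x$sigma_group, x$sigma_resid))
  cat(sprintf("  logLik = %.3f, AIC = %.2f (npar %d, n %d)%s\n", x$logLik, x$AIC,
              x$npar, x$n, if (x$converged) "" else "  [convergence flagged]"))
  invisible(x)
}

#' @export
coef.stock_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
logLik.stock_fit <- function(object, ...) {
  structure(object$logLik, df = object$npar, nobs = object$n, class = "logLik")
}

#' @export
AIC.stock_fit <- function(object, ..., k = 2) -2 * object$logLik + k * object$npar

#' @export
summary.stock_fit <- function(object, ...) {
  tab <- object$coefficients
  tab$z <- tab$estimate / tab$se
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  object$coefficients <- tab
  class(object) <- c("summary.stock_fit", "stock_fit")
  object
}

#' @export
predict.stock_fit <- function(object, newdata = NULL, ...) {
  if (object$mixed) {
    if (is.null(newdata)) stats::predict(object$fit)
    else stats::predict(object$fit, newdata = newdata, re.form = NA)
  } else stats::predict(object$fit, newdata = newdata)
}

#' @export
residuals.stock_fit <- function(object, ...) stats::residuals(object$fit)

#' Wald confidence interval with scale transformation
#'
#' Builds `estimate +/- 1.96 * se` and maps point and limits to the reporting
#' scale: `"exp"` for multiplicative factors, `"percent"` for
#' `100*(exp(x)-1)`, `"plogis"` for proportions, `"identity"` for none.
#'
#' @param estimate,se estimate and its standard error (`se >= 0`).
#' @param transform one of `"identity"`, `"exp"`, `"percent"`, `"plogis"`.
#' @param level confidence level (default 0.95 uses the 1.96 multiplier).
#' @return named numeric: `point`, `lower`, `upper`.
#' @export
wald_ci_transform <- function(estimate, se, transform = c("identity", "exp",
                                                          "percent", "plogis"),
                              level = 0.95) {
  stop_if(any(se < 0), "'se' must be >= 0")
  transform <- match.arg(transform)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (level == 0.95) z <- 1.96
  raw <- c(point = estimate, lower = estimate - z * se, upper = estimate + z * se)
  f <- switch(transform, identity = identity, exp = exp,
              percent = function(x) 100 * (exp(x) - 1), plogis = stats::plogis)
  f(raw)
}

#' Rank candidate model specifications by AIC
#'
#' Fits every candidate by maximum likelihood on the common complete-case
#' observation set and returns them sorted by AIC with differences to the
#' best.
#'
#' @param specs named list of fixed-effects formulas.
#' @param data data frame; rows with missing values in any candidate's
#'   variables are dropped for all candidates so AICs are comparable.
#' @param random grouping column for the random intercept (or `NULL`).
#' @param method passed to [fit_lmm()].
#' @return An object of class `aic_ladder`: a ranked data frame plus the fits.
#' @export
select_by_aic <- function(specs, data, random = "brood_year",
                          method = "mixed") {
  stop_if(length(specs) < 2, "need at least two candidate specifications")
  if (is.null(names(specs)) || any(names(specs) == ""))
    names(specs) <- paste0("model", seq_along(specs))
  vars <- unique(c(unlist(lapply(specs, all.vars)), random))
  vars <- intersect(vars, names(data))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  stop_if(!any(cc), "no complete observations across candidates")
  dat <- data[cc, , drop = FALSE]
  fits <- lapply(specs, fit_lmm, data = dat, random = random, method = method)
  tab <- data.frame(model = names(specs),
                    formula = vapply(specs, function(f)
                      deparse(f, width.cutoff = 500), ""),
                    npar = vapply(fits, `[[`, 0, "npar"),
                    logLik = vapply(fits, `[[`, 0, "logLik"),
                    AIC = vapply(fits, `[[`, 0, "AIC"),
                    stringsAsFactors = FALSE)
  ord <- order(tab$AIC)
  tab <- tab[ord, ]; fits <- fits[ord]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, n = nrow(dat)), class = "aic_ladder")
}

#' @export
print.aic_ladder <- function(x, ...) {
  cat(sprintf("AIC model selection over %d candidates (n = %d, ML fits)\n",
              nrow(x$table), x$n))
  tab <- x$table
  tab$logLik <- round(tab$logLik, 2); tab$AIC <- round(tab$AIC, 2)
  tab$dAIC <- round(tab$dAIC, 2)
  print(tab[, c("model", "npar", "logLik", "AIC", "dAIC")], row.names = FALSE)
  invisible(x)
}

#' Best fit from an AIC ladder
#' @param ladder an `aic_ladder`.
#' @return the `stock_fit` with the lowest AIC.
#' @export
best_model <- function(ladder) ladder$fits[[1]]
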