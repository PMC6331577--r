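#' Contrast introgression between wild-born and hatchery-reared spawners
#'
#' Fits the run-year contrast model for individual proportion farmed ancestry
#' on the logit scale:
#' \deqn{\mathrm{logit}(P_{ind,ij}) = a_i + b_i H_{ij} + e_{ij},}
#' where `a_i` is the annual wild-born mean (logit), `b_i` the annual
#' wild-vs-hatchery contrast, `H` is 0 for wild-born and 1 for
#' hatchery-reared, and `e` is an iid normal observation-level effect
#' absorbing overdispersion. Proportions at 0 or 1 are nudged inward by 1e-6
#' before the logit. Each year's contrast is tested with a Wald z-test at
#' `alpha`; years observed for only one origin are reported untestable. Group
#' grand means are the across-year averages of the fitted year means,
#' back-transformed to the proportion scale.
#'
#' @param data data frame with `run_year`, `p_ind` and either `hatchery`
#'   (0/1) or `origin` ("wild"/"hatchery").
#' @param alpha significance level for the per-year stars (default 0.05).
#' @return An object of class `introgression_contrast`: per-year table
#'   (`a`, `b`, `se_b`, `z`, `p`, `significant`), overdispersion SD, grand
#'   means per group on the proportion scale, and counts.
#' @export
fit_introgression_glmm <- function(data, alpha = 0.05) {
  stop_if(!"p_ind" %in% names(data), "data needs a 'p_ind' column")
  stop_if(!"run_year" %in% names(data), "data needs a 'run_year' column")
  if (!"hatchery" %in% names(data)) {
    stop_if(!"origin" %in% names(data), "data needs 'hatchery' or 'origin'")
    data$hatchery <- as.integer(data$origin == "hatchery")
  }
  p <- pmin(pmax(data$p_ind, 1e-6), 1 - 1e-6)
  y <- stats::qlogis(p)
  yr <- factor(data$run_year)
  H <- data$hatchery
  both <- tapply(H, yr, function(h) length(unique(h)) == 2)
  dat <- data.frame(y = y, yr = yr, H = H)
  sub <- dat[both[as.character(dat$yr)], , drop = FALSE]
  stop_if(nrow(sub) == 0, "no run year contains both origins")
  sub$yr <- droplevels(sub$yr)
  fit <- stats::lm(y ~ 0 + yr + yr:H, data = sub)
  cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  lev <- levels(sub$yr)
  a <- cf[paste0("yr", lev)]
  b <- cf[paste0("yr", lev, ":H")]
  se_b <- se[paste0("yr", lev, ":H")]
  z <- b / se_b
  pval <- 2 * stats::pnorm(-abs(z))
  years <- data.frame(run_year = lev,
                      n_wild = as.integer(tapply(sub$H == 0, sub$yr, sum)),
                      n_hatchery = as.integer(tapply(sub$H == 1, sub$yr, sum)),
                      a = as.numeric(a), b = as.numeric(b),
                      se_b = as.numeric(se_b), z = as.numeric(z),
                      p = as.numeric(pval),
                      significant = as.numeric(pval) <= alpha,
                      stringsAsFactors = FALSE)
  untestable <- setdiff(levels(yr), lev)
  out <- list(years = years, untestable_years = untestable,
              sigma_overdispersion = stats::sigma(fit),
              grand_means = c(wild = mean(stats::plogis(years$a)),
                              hatchery = mean(stats::plogis(years$a + years$b))),
              alpha = alpha, n = nrow(sub), fit = fit)
  class(out) <- "introgression_contrast"
  out
}

#' @export
print.introgression_contrast <- function(x, ...) {
  cat(sprintf("Run-year introgression contrast (n = %d, %d testable years, %d untestable)\n",
              x$n, nrow(x$years), length(x$untestable_years)))
  cat(sprintf("  grand mean proportion farmed ancestry: wild %.3f, hatchery %.3f\n",
              x$grand_means[["wild"]], x$grand_means[["hatchery"]]))
  cat(sprintf("  overdispersion SD (logit scale): %.3f\n", x$sigma_overdispersion))
  cat(sprintf("  years with a significant contrast at alpha %.2f: %d of %d\n",
              x$alpha, sum(x$years$significant), nrow(x$years)))
  invisible(x)
}

#' @export
coef.introgression_contrast <- function(object, ...) {
  stats::setNames(c(object$years$a, object$years$b),
                  c(paste0("a_", object$years$run_year),
                    paste0("b_", object$years$run_year)))
}
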