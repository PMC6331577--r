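#' Fit the recaptured-offspring count models
#'
#' Reproduces the two reported specifications for the log number of recaptured
#' adult offspring per broodstock pair: (i) environmental background of the
#' dam plus background-specific slopes of pair introgression, and (ii) the
#' same plus log egg number (the best model). Both use a brood-year random
#' intercept and ML estimation; the fuller model's AIC improvement is
#' reported. Optionally the full candidate ladder (background and interaction
#' structures with and without egg covariates) is fitted instead.
#'
#' @param family data frame with one row per broodstock pair: `n_offspring`,
#'   `pair_introgression`, `dam_background` ("wild"/"hatchery"),
#'   `sire_background`, `egg_number`, `egg_size`, `brood_year`.
#' @param method `"mixed"` (default; brood-year random intercept) or
#'   `"fixed"` (the least-squares variant).
#' @param ladder fit the wider candidate set and select by AIC?
#' @return list of class `count_suite`: `base` and `best` fits (`stock_fit`),
#'   `dAIC` (AIC of base minus best), and the `aic_ladder` when requested.
#' @export
fit_count_model_suite <- function(family, method = "mixed", ladder = FALSE) {
  need <- c("n_offspring", "pair_introgression", "dam_background", "brood_year",
            "egg_number")
  absent <- setdiff(need, names(family))
  stop_if(length(absent) > 0, "family table lacks: ", paste(absent, collapse = ", "))
  dat <- family
  dat$dam_background <- factor(dat$dam_background, levels = c("wild", "hatchery"))
  dat$log_count <- log(dat$n_offspring)
  dat$log_eggs <- log(dat$egg_number)
  f_base <- log_count ~ dam_background + dam_background:pair_introgression
  f_best <- log_count ~ dam_background + dam_background:pair_introgression + log_eggs
  base <- fit_lmm(f_base, dat, random = "brood_year", method = method)
  best <- fit_lmm(f_best, dat, random = "brood_year", method = method)
  out <- list(base = base, best = best, dAIC = base$AIC - best$AIC)
  if (ladder) {
    stop_if(!"egg_size" %in% names(dat), "ladder fits need an 'egg_size' column")
    specs <- list(
      null = log_count ~ 1,
      background = log_count ~ dam_background,
      both_backgrounds = log_count ~ dam_background + sire_background,
      introgression = log_count ~ dam_background + pair_introgression,
      interaction = f_base,
      interaction_eggs = f_best,
      interaction_eggs_size = stats::update(f_best, . ~ . + log(egg_size)))
    out$ladder <- select_by_aic(specs, dat, random = "brood_year", method = method)
  }
  class(out) <- "count_suite"
  out
}

#' @export
print.count_suite <- function(x, ...) {
  cat("Recaptured-offspring count models\n")
  cat("-- background + background:introgression --\n"); print(x$base)
  cat("-- + log egg number (best) --\n"); print(x$best)
  cat(sprintf("AIC improvement from log egg number: %.2f\n", x$dAIC))
  if (!is.null(x$ladder)) print(x$ladder)
  invisible(x)
}

#' Fit the egg-size and egg-number models
#'
#' Egg size (log ml): dam background + log dam weight + background-specific
#' introgression slopes. Egg number (log): dam background + log dam weight.
#' Both with a brood-year random intercept, ML.
#'
#' @param dams data frame with one row per dam: `egg_size`, `egg_number`,
#'   `dam_weight`, `dam_background`, `introgression`, `brood_year`.
#' @param method passed to [fit_lmm()].
#' @return list of class `egg_models` with `size` and `number` fits.
#' @export
fit_egg_models <- function(dams, method = "mixed") {
  need <- c("egg_size", "egg_number", "dam_weight", "dam_background",
            "introgression", "brood_year")
  absent <- setdiff(need, names(dams))
  stop_if(length(absent) > 0, "dam table lacks: ", paste(absent, collapse = ", "))
  dat <- dams
  dat$dam_background <- factor(dat$dam_background, levels = c("wild", "hatchery"))
  size <- fit_lmm(log(egg_size) ~ dam_background + log(dam_weight) +
                    dam_background:introgression,
                  dat, random = "brood_year", method = method)
  number <- fit_lmm(log(egg_number) ~ dam_background + log(dam_weight),
                    dat, random = "brood_year", method = method)
  structure(list(size = size, number = number), class = "egg_models")
}

#' @export
print.egg_models <- function(x, ...) {
  cat("-- egg size (log ml) --\n"); print(x$size)
  cat("-- egg number (log) --\n"); print(x$number)
  invisible(x)
}

#' Fit the smolt-length model
#'
#' Log back-calculated smolt length as response, a separate intercept per sea
#' age, a common introgression slope, and a brood-year random intercept (ML).
#' The introgression effect is reported as the percent length difference
#' between fully introgressed and non-introgressed fish,
#' `100 * (exp(slope) - 1)`, with its 95% Wald interval.
#'
#' @param adults data frame with `smolt_length` (or `bc_smolt_length`),
#'   `sea_age`, `introgression`, `brood_year`.
#' @param method passed to [fit_lmm()].
#' @return a `stock_fit` with extra elements `percent_effect` (named point /
#'   lower / upper).
#' @export
fit_smolt_length_model <- function(adults, method = "mixed") {
  dat <- adults
  if (!"smolt_length" %in% names(dat) && "bc_smolt_length" %in% names(dat))
    dat$smolt_length <- dat$bc_smolt_length
  need <- c("smolt_length", "sea_age", "introgression", "brood_year")
  absent <- setdiff(need, names(dat))
  stop_if(length(absent) > 0, "adult table lacks: ", paste(absent, collapse = ", "))
  dat$sea_age <- factor(dat$sea_age)
  form <- if (nlevels(dat$sea_age) > 1)
    log(smolt_length) ~ sea_age + introgression else
    log(smolt_length) ~ introgression
  fit <- fit_lmm(form, dat, random = "brood_year", method = method)
  i <- match("introgression", fit$coefficients$term)
  fit$percent_effect <- wald_ci_transform(fit$coefficients$estimate[i],
                                          fit$coefficients$se[i], "percent")
  fit
}
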