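#' Generating parameters for a synthetic stocking study
#'
#' Bundles every effect size and noise level used by the synthetic-data
#' generators. The defaults are the study conditions: the best-model
#' coefficients of the recaptured-offspring count model (log scale), the egg
#' model factors, the smolt-size effects and group means, the broodstock and
#' run-year introgression means, and the genotyping error/missingness levels.
#' All simulated quantities retain their generating values so recovery tests
#' are well posed.
#'
#' @param beta_intercept,beta_dam_hatchery,beta_introgression_wild_dam,beta_introgression_hatchery_dam,beta_log_eggs
#'   coefficients of the offspring-count model on the natural-log scale.
#' @param egg_size_factor_hatchery multiplicative egg-size effect of a
#'   hatchery-reared dam relative to wild-born.
#' @param egg_size_factor_introgression multiplicative egg-size effect of full
#'   farmed ancestry in a wild-born dam.
#' @param smolt_pct_effect named numeric (hatchery, wild): percent smolt-length
#'   difference at full farmed ancestry.
#' @param smolt_mean_length named numeric (hatchery, wild): group mean smolt
#'   length, mm.
#' @param introgression_means named numeric (wild, hatchery): mean proportion
#'   farmed ancestry of wild-born and hatchery-reared adults in the run-year
#'   samples.
#' @param broodstock_introgression_means named numeric (wild, hatchery): mean
#'   farmed ancestry of wild-born and hatchery-reared broodstock.
#' @param introgression_concentration Beta concentration of individual
#'   ancestry around its group mean.
#' @param prop_dam_hatchery,prop_sire_hatchery probability that a dam/sire is
#'   hatchery-reared.
#' @param sigma_resid,sigma_year residual and brood-year SD of the log-count
#'   model.
#' @param sigma_egg_size,sigma_egg_number residual SD of the log egg models.
#' @param sigma_smolt,sigma_year_smolt residual and year SD of the log
#'   smolt-length model.
#' @param sigma_logit_year,sigma_logit_ind year and individual SD of run-year
#'   introgression on the logit scale.
#' @param dam_weight_meanlog,dam_weight_sdlog lognormal dam wet weight (g).
#' @param egg_number_intercept,egg_number_weight_slope,egg_number_hatchery
#'   log egg-number model: intercept, slope on log dam weight, hatchery-dam
#'   effect.
#' @param egg_size_intercept,egg_size_weight_slope log egg-size model (ml):
#'   intercept and slope on log dam weight.
#' @param sea_age list with elements `a`, `b`, `d` (length-2 numeric: the two
#'   log-odds contrasts against the 3+ baseline) and `sigma_t` (year SD).
#' @param genotyping_error_rate per-genotype probability that one allele is
#'   flipped in an offspring call.
#' @param missing_rate per-genotype dropout probability in offspring calls.
#' @return An object of class `effect_config` (a validated list).
#' @export
effect_config <- function(beta_intercept = -4.5564,
                          beta_dam_hatchery = 0.5560,
                          beta_introgression_wild_dam = 1.5145,
                          beta_introgression_hatchery_dam = -0.5018,
                          beta_log_eggs = 0.7069,
                          egg_size_factor_hatchery = 0.86,
                          egg_size_factor_introgression = 0.67,
                          smolt_pct_effect = c(hatchery = 6.2, wild = 5.0),
                          smolt_mean_length = c(hatchery = 232, wild = 152),
                          introgression_means = c(wild = 0.092, hatchery = 0.27),
                          broodstock_introgression_means = c(wild = 0.113, hatchery = 0.303),
                          introgression_concentration = 10,
                          prop_dam_hatchery = 0.55,
                          prop_sire_hatchery = 0.65,
                          sigma_resid = 0.7,
                          sigma_year = 0.2,
                          sigma_egg_size = 0.08,
                          sigma_egg_number = 0.18,
                          sigma_smolt = 0.13,
                          sigma_year_smolt = 0.03,
                          sigma_logit_year = 0.3,
                          sigma_logit_ind = 0.8,
                          dam_weight_meanlog = log(5100),
                          dam_weight_sdlog = 0.3,
                          egg_number_intercept = log(1.45),
                          egg_number_weight_slope = 1,
                          egg_number_hatchery = -0.12,
                          egg_size_intercept = -3.2745,
                          egg_size_weight_slope = 0.10,
                          sea_age = list(a = c(0.3, 0.8), b = c(0, 0),
                                         d = c(0, 0), sigma_t = 0.4),
                          genotyping_error_rate = 0.002,
                          missing_rate = 0.04) {
  cfg <- as.list(environment())
  sig <- c("sigma_resid", "sigma_year", "sigma_egg_size", "sigma_egg_number",
           "sigma_smolt", "sigma_year_smolt", "sigma_logit_year", "sigma_logit_ind")
  for (s in sig) stop_if(cfg[[s]] < 0 || is.na(cfg[[s]]),
                         sprintf("'%s' must be a non-negative variance component", s))
  check_prob(genotyping_error_rate, "genotyping_error_rate")
  check_prob(missing_rate, "missing_rate")
  check_prob(introgression_means, "introgression_means", open = TRUE)
  check_prob(broodstock_introgression_means, "broodstock_introgression_means", open = TRUE)
  check_prob(prop_dam_hatchery, "prop_dam_hatchery")
  check_prob(prop_sire_hatchery, "prop_sire_hatchery")
  stop_if(cfg$sea_age$sigma_t < 0, "sea_age$sigma_t must be >= 0")
  stop_if(cfg$introgression_concentration <= 0, "'introgression_concentration' must be > 0")
  class(cfg) <- "effect_config"
  cfg
}

#' @export
print.effect_config <- function(x, ...) {
  cat("Synthetic-study effect configuration\n")
  cat(sprintf("  count model betas: %.4f / %.4f / %.4f / %.4f / %.4f\n",
              x$beta_intercept, x$beta_dam_hatchery, x$beta_introgression_wild_dam,
              x$beta_introgression_hatchery_dam, x$beta_log_eggs))
  cat(sprintf("  broodstock ancestry means (wild/hatchery): %.3f / %.3f\n",
              x$broodstock_introgression_means[["wild"]],
              x$broodstock_introgression_means[["hatchery"]]))
  cat(sprintf("  run-year ancestry means (wild/hatchery): %.3f / %.3f\n",
              x$introgression_means[["wild"]], x$introgression_means[["hatchery"]]))
  cat(sprintf("  error/missing rates: %.4f / %.3f\n",
              x$genotyping_error_rate, x$missing_rate))
  invisible(x)
}

#' Simulate nuclear genotypes for a batch of admixed individuals
#'
#' Genotype matrix (individuals x nuclear loci): two allele draws per locus
#' from the mixture frequency `true_d * farmed + (1 - true_d) * wild`.
#'
#' @param panel a [ref_panel()].
#' @param true_d vector of admixture proportions, one per individual.
#' @return integer matrix with locus column names.
#' @export
simulate_genotypes <- function(panel, true_d) {
  check_prob(true_d, "true_d")
  nuc <- panel[!panel$mt, ]
  n <- length(true_d); L <- nrow(nuc)
  pmix <- outer(true_d, nuc$farmed_freq) + outer(1 - true_d, nuc$wild_freq)
  g <- matrix(stats::rbinom(n * L, 2, pmix), n, L)
  dimnames(g) <- list(sprintf("ind%04d", seq_len(n)), nuc$locus)
  g
}

#' Simulate haploid mtDNA haplotypes
#'
#' Source population is farmed with probability `true_d`, wild otherwise;
#' each mt locus is then drawn from that population's frequency.
#'
#' @inheritParams simulate_genotypes
#' @return 0/1 integer matrix (individuals x mt loci).
#' @export
simulate_mt <- function(panel, true_d) {
  mt <- panel[panel$mt, ]
  n <- length(true_d); L <- nrow(mt)
  if (L == 0) return(matrix(integer(0), n, 0))
  src <- stats::rbinom(n, 1, true_d)
  f <- ifelse(outer(src, rep(1, L)) == 1,
              matrix(mt$farmed_freq, n, L, byrow = TRUE),
              matrix(mt$wild_freq, n, L, byrow = TRUE))
  h <- matrix(stats::rbinom(n * L, 1, f), n, L)
  dimnames(h) <- list(sprintf("ind%04d", seq_len(n)), mt$locus)
  h
}

#' Simulate one admixed individual
#'
#' Draws nuclear genotypes as two allele draws per locus from the mixture
#' frequency `true_d * farmed + (1 - true_d) * wild`, and an mtDNA haplotype
#' from the farmed source with probability `true_d`, else the wild source.
#'
#' @param panel a [ref_panel()].
#' @param true_d admixture proportion in \[0,1\]; stored as ground truth.
#' @param seed optional integer seed.
#' @return list with `genotypes` (named integer vector over nuclear loci),
#'   `mt` (named 0/1 vector over mt loci) and `true_d`.
#' @export
simulate_individual <- function(panel, true_d, seed = NULL) {
  stop_if(length(true_d) != 1 || is.na(true_d) || true_d < 0 || true_d > 1,
          "'true_d' must be a scalar in [0,1]")
  with_substream(seed, "individual", {
    list(genotypes = simulate_genotypes(panel, true_d)[1, ],
         mt = if (sum(panel$mt)) simulate_mt(panel, true_d)[1, ] else integer(0),
         true_d = true_d)
  })
}

## Mendelian segregation: each parent transmits one allele per locus.
transmit <- function(g) {
  het <- !is.na(g) & g == 1L
  a <- ifelse(g == 2L, 1L, 0L)
  a[het] <- stats::rbinom(sum(het), 1, 0.5)
  a
}

mendelian_offspring <- function(dam_g, sire_g) transmit(dam_g) + transmit(sire_g)

## symmetric per-call error: with prob `rate` one randomly chosen allele of the
## call is flipped (0 -> 1, 2 -> 1, 1 -> 0 or 2); then dropouts at `missing`.
inject_errors <- function(g, rate, missing) {
  if (rate > 0) {
    hit <- which(stats::runif(length(g)) < rate & !is.na(g))
    if (length(hit)) {
      old <- g[hit]
      up <- stats::rbinom(length(hit), 1, 0.5) == 1
      newg <- ifelse(old == 1L, ifelse(up, 2L, 0L), 1L)
      g[hit] <- newg
    }
  }
  if (missing > 0) g[stats::runif(length(g)) < missing] <- NA
  g
}

rbeta_mean <- function(n, mean, conc) stats::rbeta(n, mean * conc, (1 - mean) * conc)

#' Simulate a broodstock study: crosses, egg production, recaptured offspring
#'
#' Generates `n_pairs` dam-sire crosses spread over the given brood years.
#' Dams and sires are wild-born or hatchery-reared with the configured
#' probabilities and carry Beta-distributed farmed ancestry around their
#' group mean. Egg size and egg number follow the log-scale egg models; the
#' expected log number of recaptured adult offspring follows the count-model
#' linear predictor (background effects, background-specific ancestry slopes,
#' log egg number) plus a brood-year random effect and a residual. Realised
#' counts are the rounded lognormal draw, with zeros redrawn so every retained
#' family has at least one recapture. With `genotypes = TRUE`, parental
#' genotypes are drawn at their true ancestry and offspring genotypes by
#' Mendelian segregation, after which offspring calls receive allele-flip
#' errors and dropouts at the configured rates; offspring mtDNA is the dam's
#' haplotype with dropouts only. Offspring also receive sex, sea age (from the
#' sea-age model), back-calculable scale readings and smolt lengths (from the
#' growth model, hatchery calibration, since recaptured offspring are
#' hatchery-reared).
#'
#' @param config an [effect_config()].
#' @param n_pairs number of dam-sire pairs (default 85).
#' @param years brood years (default 2005:2011).
#' @param seed integer seed.
#' @param panel a [ref_panel()]; required when `genotypes = TRUE`.
#' @param genotypes draw genotypes for parents and offspring?
#' @return A list of class `sim_study`: `crosses` (one row per pair, with the
#'   generating truth), `broodstock` (roster with sex, year, background, true
#'   ancestry), `offspring` (one row per recaptured offspring with true parent
#'   ids and phenotypes), genotype/mtDNA matrices when requested, `panel`, and
#'   the `config` used.
#' @export
simulate_crosses <- function(config = effect_config(), n_pairs = 85,
                             years = 2005:2011, seed = 1,
                             panel = NULL, genotypes = FALSE) {
  stop_if(n_pairs < 1, "'n_pairs' must be >= 1")
  stopifnot(inherits(config, "effect_config"))
  if (genotypes) stop_if(is.null(panel), "'panel' is required when genotypes = TRUE")
  with_substream(seed, "crosses", {
    yr <- sort(rep_len(years, n_pairs))
    u_year <- stats::rnorm(length(years), 0, config$sigma_year)
    names(u_year) <- as.character(years)
    bm <- config$broodstock_introgression_means
    dam_h <- stats::rbinom(n_pairs, 1, config$prop_dam_hatchery)
    sire_h <- stats::rbinom(n_pairs, 1, config$prop_sire_hatchery)
    conc <- config$introgression_concentration
    d_dam <- rbeta_mean(n_pairs, ifelse(dam_h == 1, bm[["hatchery"]], bm[["wild"]]), conc)
    d_sire <- rbeta_mean(n_pairs, ifelse(sire_h == 1, bm[["hatchery"]], bm[["wild"]]), conc)
    weight <- stats::rlnorm(n_pairs, config$dam_weight_meanlog, config$dam_weight_sdlog)
    ## egg models (log scale); ancestry affects size in wild-born dams only
    log_size <- config$egg_size_intercept +
      config$egg_size_weight_slope * log(weight) +
      log(config$egg_size_factor_hatchery) * dam_h +
      log(config$egg_size_factor_introgression) * d_dam * (1 - dam_h) +
      stats::rnorm(n_pairs, 0, config$sigma_egg_size)
    log_num <- config$egg_number_intercept +
      config$egg_number_weight_slope * log(weight) +
      config$egg_number_hatchery * dam_h +
      stats::rnorm(n_pairs, 0, config$sigma_egg_number)
    egg_size <- exp(log_size)
    egg_number <- round(exp(log_num))
    pair_d <- (d_dam + d_sire) / 2
    mu <- config$beta_intercept +
      config$beta_dam_hatchery * dam_h +
      config$beta_introgression_wild_dam * pair_d * (1 - dam_h) +
      config$beta_introgression_hatchery_dam * pair_d * dam_h +
      config$beta_log_eggs * log(egg_number) +
      u_year[as.character(yr)]
    n_off <- round(exp(mu + stats::rnorm(n_pairs, 0, config$sigma_resid)))
    for (i in 1:50) {                      # zero-truncation: redraw empty families
      z <- which(n_off < 1)
      if (!length(z)) break
      n_off[z] <- round(exp(mu[z] + stats::rnorm(length(z), 0, config$sigma_resid)))
    }
    n_off[n_off < 1] <- 1L
    crosses <- data.frame(
      pair_id = sprintf("pair%03d", seq_len(n_pairs)),
      dam = sprintf("dam%03d", seq_len(n_pairs)),
      sire = sprintf("sire%03d", seq_len(n_pairs)),
      brood_year = yr,
      dam_background = ifelse(dam_h == 1, "hatchery", "wild"),
      sire_background = ifelse(sire_h == 1, "hatchery", "wild"),
      true_d_dam = d_dam, true_d_sire = d_sire, true_pair_d = pair_d,
      dam_weight = weight, egg_size = egg_size, egg_number = egg_number,
      mu_log_count = mu, n_offspring = as.integer(n_off),
      stringsAsFactors = FALSE)
    broodstock <- data.frame(
      id = c(crosses$dam, crosses$sire),
      sex = rep(c("F", "M"), each = n_pairs),
      brood_year = rep(yr, 2),
      background = c(crosses$dam_background, crosses$sire_background),
      true_d = c(d_dam, d_sire), stringsAsFactors = FALSE)
    total <- sum(n_off)
    off_pair <- rep(seq_len(n_pairs), n_off)
    offspring <- data.frame(
      id = sprintf("off%04d", seq_len(total)),
      pair_id = crosses$pair_id[off_pair],
      true_dam = crosses$dam[off_pair],
      true_sire = crosses$sire[off_pair],
      brood_year = crosses$brood_year[off_pair],
      true_d = (d_dam[off_pair] + d_sire[off_pair]) / 2,
      sex = sample(c("F", "M"), total, replace = TRUE),
      stringsAsFactors = FALSE)
    offspring <- cbind(offspring,
                       simulate_growth(config, offspring$true_d,
                                       offspring$brood_year, origin = "hatchery"))
    out <- list(crosses = crosses, broodstock = broodstock, offspring = offspring,
                config = config, panel = panel, year_effects = u_year)
    if (genotypes) {
      g_par <- simulate_genotypes(panel, broodstock$true_d)
      rownames(g_par) <- broodstock$id
      mt_par <- simulate_mt(panel, broodstock$true_d)
      rownames(mt_par) <- broodstock$id
      L <- ncol(g_par)
      g_off <- matrix(NA_integer_, total, L, dimnames = list(offspring$id, colnames(g_par)))
      for (i in seq_len(total)) {
        g_off[i, ] <- mendelian_offspring(g_par[offspring$true_dam[i], ],
                                          g_par[offspring$true_sire[i], ])
      }
      g_off <- inject_errors(g_off, config$genotyping_error_rate, config$missing_rate)
      mt_off <- mt_par[offspring$true_dam, , drop = FALSE]
      rownames(mt_off) <- offspring$id
      if (config$missing_rate > 0)
        mt_off[stats::runif(length(mt_off)) < config$missing_rate] <- NA
      out$genotypes <- list(broodstock = g_par, broodstock_mt = mt_par,
                            offspring = g_off, offspring_mt = mt_off)
    }
    class(out) <- "sim_study"
    out
  })
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Synthetic broodstock study: %d pairs, %d brood years, %d recaptured offspring\n",
              nrow(x$crosses), length(unique(x$crosses$brood_year)), nrow(x$offspring)))
  cat(sprintf("  mean family size %.1f (range %d-%d)\n", mean(x$crosses$n_offspring),
              min(x$crosses$n_offspring), max(x$crosses$n_offspring)))
  if (!is.null(x$genotypes)) cat("  genotypes attached\n")
  invisible(x)
}

## sea age + smolt growth phenotypes for adults of one origin
simulate_growth <- function(config, true_d, year, origin = c("hatchery", "wild")) {
  origin <- match.arg(origin)
  n <- length(true_d)
  sa <- config$sea_age
  yrs <- sort(unique(year))
  t1 <- stats::rnorm(length(yrs), 0, sa$sigma_t); names(t1) <- as.character(yrs)
  t2 <- stats::rnorm(length(yrs), 0, sa$sigma_t); names(t2) <- as.character(yrs)
  dbar <- tapply(true_d, year, mean)[as.character(year)]
  dgrand <- mean(tapply(true_d, year, mean))
  e1 <- sa$a[1] + sa$b[1] * true_d + sa$d[1] * (dbar - dgrand) + t1[as.character(year)]
  e2 <- sa$a[2] + sa$b[2] * true_d + sa$d[2] * (dbar - dgrand) + t2[as.character(year)]
  den <- 1 + exp(e1) + exp(e2)
  pr <- cbind(exp(e1) / den, exp(e2) / den, 1 / den)
  sea_age <- apply(pr, 1, function(p) sample(c("1", "2", "3+"), 1, prob = p))
  ## log smolt length: origin-specific intercept centred so the group mean
  ## matches the configured mean at the group's mean ancestry
  slope <- log(1 + config$smolt_pct_effect[[origin]] / 100)
  mean_d <- config$introgression_means[[if (origin == "hatchery") "hatchery" else "wild"]]
  icpt <- log(config$smolt_mean_length[[origin]]) - slope * mean_d
  sa_off <- c("1" = 0, "2" = -0.01, "3+" = -0.02)[sea_age]
  uy <- stats::rnorm(length(yrs), 0, config$sigma_year_smolt); names(uy) <- as.character(yrs)
  log_smolt <- icpt + slope * true_d + sa_off + uy[as.character(year)] +
    stats::rnorm(n, 0, config$sigma_smolt)
  smolt_length <- exp(log_smolt)
  capture_length <- c("1" = 550, "2" = 750, "3+" = 900)[sea_age] *
    stats::rlnorm(n, 0, 0.06)
  total_radius <- capture_length * stats::runif(n, 0.048, 0.058)
  smolt_radius <- total_radius * smolt_length / capture_length  # proportional scale growth
  data.frame(sea_age = sea_age, smolt_length = smolt_length,
             capture_length = capture_length, total_radius = total_radius,
             smolt_radius = smolt_radius, stringsAsFactors = FALSE)
}

#' Simulate returning adults of one origin with growth phenotypes
#'
#' Adults carry Beta-distributed farmed ancestry around their origin's
#' run-year mean, a birth (brood) year, a sea age drawn from the
#' multinomial-logit sea-age model, and a smolt length drawn from the log-scale
#' growth model (with scale radii consistent with proportional
#' back-calculation).
#'
#' @param config an [effect_config()].
#' @param n number of adults.
#' @param origin "hatchery" or "wild".
#' @param years birth years.
#' @param seed integer seed.
#' @return data frame, one row per adult, including `true_d`.
#' @export
simulate_adults <- function(config = effect_config(), n = 500,
                            origin = c("hatchery", "wild"),
                            years = 2001:2012, seed = 1) {
  origin <- match.arg(origin)
  with_substream(seed, paste0("adults_", origin), {
    mean_d <- config$introgression_means[[if (origin == "hatchery") "hatchery" else "wild"]]
    true_d <- rbeta_mean(n, mean_d, config$introgression_concentration)
    year <- sample(years, n, replace = TRUE)
    cbind(data.frame(id = sprintf("ad%05d", seq_len(n)), origin = origin,
                     birth_year = year, true_d = true_d,
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     stringsAsFactors = FALSE),
          simulate_growth(config, true_d, year, origin))
  })
}

#' Simulate run-year samples of wild-born and hatchery-reared adults
#'
#' Per run year, draws wild-born and hatchery-reared adults whose proportion
#' farmed ancestry is generated on the logit scale: group mean at the logit of
#' the configured run-year means, plus a shared normal year effect and an
#' individual normal deviation (the overdispersion the contrast model absorbs).
#'
#' @param config an [effect_config()].
#' @param n_years number of run years (default 20).
#' @param n_per_group adults per origin per year (default 70).
#' @param seed integer seed.
#' @return data frame with `run_year`, `origin`, `hatchery` (0/1) and `p_ind`.
#' @export
simulate_run_years <- function(config = effect_config(), n_years = 20,
                               n_per_group = 70, seed = 1) {
  stop_if(n_years < 1, "'n_years' must be >= 1")
  stopifnot(inherits(config, "effect_config"))
  with_substream(seed, "run_years", {
    m <- config$introgression_means
    yrs <- seq_len(n_years) + 1985
    uy <- stats::rnorm(n_years, 0, config$sigma_logit_year)
    out <- vector("list", n_years)
    for (i in seq_len(n_years)) {
      lw <- stats::qlogis(m[["wild"]]) + uy[i] +
        stats::rnorm(n_per_group, 0, config$sigma_logit_ind)
      lh <- stats::qlogis(m[["hatchery"]]) + uy[i] +
        stats::rnorm(n_per_group, 0, config$sigma_logit_ind)
      out[[i]] <- data.frame(
        run_year = yrs[i],
        origin = rep(c("wild", "hatchery"), each = n_per_group),
        hatchery = rep(c(0L, 1L), each = n_per_group),
        p_ind = stats::plogis(c(lw, lh)), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
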