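#' Configuration for an end-to-end synthetic study run
#'
#' @param panel list of [simulate_panel()] arguments (locus counts,
#'   divergence).
#' @param effects an [effect_config()].
#' @param n_pairs number of broodstock pairs.
#' @param brood_years brood years of the crosses.
#' @param run_years list with `n_years` and `n_per_group` for the run-year
#'   samples.
#' @param n_growth_adults hatchery-reared adults simulated for the smolt model.
#' @param max_mismatch,missing_threshold,year_window parentage thresholds.
#' @param seed global seed; all stage substreams derive from it.
#' @return validated list of class `run_config`.
#' @export
study_config <- function(panel = list(n_diagnostic = 48, n_neutral = 33,
                                      n_mt = 15, divergence = 0.6),
                         effects = effect_config(),
                         n_pairs = 85, brood_years = 2005:2011,
                         run_years = list(n_years = 20, n_per_group = 70),
                         n_growth_adults = 800,
                         max_mismatch = 2, missing_threshold = 0.20,
                         year_window = 1, seed = 1) {
  cfg <- as.list(environment())
  errs <- character(0)
  if (!inherits(cfg$effects, "effect_config"))
    errs <- c(errs, "'effects' must be an effect_config")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed) || cfg$seed < 0)
    errs <- c(errs, "'seed' must be a single non-negative integer")
  if (cfg$n_pairs < 1) errs <- c(errs, "'n_pairs' must be >= 1")
  if (cfg$max_mismatch < 0) errs <- c(errs, "'max_mismatch' must be >= 0")
  if (cfg$missing_threshold < 0 || cfg$missing_threshold > 1)
    errs <- c(errs, "'missing_threshold' must be in [0,1]")
  if (cfg$year_window < 0) errs <- c(errs, "'year_window' must be >= 0")
  if (!all(c("n_years", "n_per_group") %in% names(cfg$run_years)) ||
      cfg$run_years$n_years < 1)
    errs <- c(errs, "'run_years' needs n_years >= 1 and n_per_group")
  stop_if(length(errs) > 0, "invalid configuration:\n  ",
          paste(errs, collapse = "\n  "))
  class(cfg) <- "run_config"
  cfg
}

#' Read and validate a run configuration from a YAML file
#'
#' Unknown keys (at the top level or inside `effects`) are rejected; all
#' schema violations are reported together.
#'
#' @param path YAML file.
#' @return a validated `run_config`.
#' @export
validate_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: ", path)
  raw <- yaml::read_yaml(path)
  raw <- raw %||% list()
  known <- setdiff(names(formals(study_config)), "")
  errs <- character(0)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    errs <- c(errs, paste("unknown keys:", paste(unknown, collapse = ", ")))
  if (!is.null(raw$effects)) {
    eff_known <- names(formals(effect_config))
    eff_unknown <- setdiff(names(raw$effects), eff_known)
    if (length(eff_unknown))
      errs <- c(errs, paste("unknown effects keys:", paste(eff_unknown, collapse = ", ")))
    if (!length(eff_unknown)) {
      ## named numeric fields arrive as YAML maps; coerce
      raw$effects <- lapply(raw$effects, function(x)
        if (is.list(x) && !is.null(names(x)) && all(vapply(x, is.numeric, TRUE)) &&
            !any(vapply(x, is.list, TRUE))) unlist(x) else x)
      raw$effects <- do.call(effect_config, raw$effects)
    }
  }
  stop_if(length(errs) > 0, "invalid configuration:\n  ",
          paste(errs, collapse = "\n  "))
  do.call(study_config, raw[setdiff(names(raw), character(0))])
}

write_stage <- function(df, outdir, name, seed) {
  if (is.null(outdir)) return(invisible(NULL))
  path <- file.path(outdir, paste0(name, ".tsv"))
  con <- file(path, "w")
  writeLines(sprintf("# stocksel %s seed=%d generated=%s",
                     as.character(utils::packageVersion("stocksel")), seed,
                     format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the full synthetic study pipeline
#'
#' Simulates a panel and a broodstock study with genotypes, estimates each
#' individual's proportion farmed ancestry from its diagnostic genotypes,
#' assigns recaptured offspring to broodstock pairs by Mendelian exclusion,
#' builds the family table with estimated pair introgression, fits the count
#' model suite, the egg models, the smolt-length model and the run-year
#' introgression contrast model, and reports estimated against generating
#' values.
#'
#' @param config a `run_config` from [study_config()] or [validate_config()].
#' @param outdir optional directory; stage tables are persisted there as
#'   tab-separated text with a seed-stamped header.
#' @return An object of class `study_report`.
#' @export
run_study <- function(config = study_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
    message("created output directory ", outdir)
  }
  panel <- do.call(simulate_panel, c(config$panel, list(seed = seed)))
  study <- simulate_crosses(config$effects, n_pairs = config$n_pairs,
                            years = config$brood_years, seed = seed,
                            panel = panel, genotypes = TRUE)
  anc_bs <- batch_estimate(study$genotypes$broodstock, panel)
  anc_off <- batch_estimate(study$genotypes$offspring, panel)
  study$broodstock$d_hat <- anc_bs$d[match(study$broodstock$id, anc_bs$id)]
  assignments <- assign_parentage(
    study$genotypes$offspring, study$offspring$brood_year, study$broodstock,
    study$genotypes$broodstock,
    offspring_mt = study$genotypes$offspring_mt,
    broodstock_mt = study$genotypes$broodstock_mt,
    max_mismatch = config$max_mismatch,
    missing_threshold = config$missing_threshold,
    year_window = config$year_window)
  family <- build_family_table(assignments, study$broodstock,
                               crosses = study$crosses, d_col = "d_hat")
  counts <- fit_count_model_suite(family)
  dams <- study$crosses
  dams$dam_background <- dams$dam_background
  dams$introgression <- study$broodstock$d_hat[match(dams$dam, study$broodstock$id)]
  eggs <- fit_egg_models(dams)
  adults <- simulate_adults(config$effects, n = config$n_growth_adults,
                            origin = "hatchery", seed = seed)
  adults <- add_back_calculated_smolt(adults)
  adults$introgression <- adults$true_d
  adults$brood_year <- adults$birth_year
  smolt <- fit_smolt_length_model(adults)
  runs <- simulate_run_years(config$effects, n_years = config$run_years$n_years,
                             n_per_group = config$run_years$n_per_group,
                             seed = seed)
  contrast <- fit_introgression_glmm(runs)
  truth <- config$effects
  recov <- data.frame(
    quantity = c("wild-dam introgression slope (log counts)",
                 "hatchery-dam background (log counts)",
                 "log egg number slope",
                 "percent smolt effect (hatchery)",
                 "grand mean ancestry (wild-born)",
                 "grand mean ancestry (hatchery-reared)"),
    truth = c(truth$beta_introgression_wild_dam, truth$beta_dam_hatchery,
              truth$beta_log_eggs, truth$smolt_pct_effect[["hatchery"]],
              truth$introgression_means[["wild"]],
              truth$introgression_means[["hatchery"]]),
    estimate = c(
      coef(counts$best)[["dam_backgroundwild:pair_introgression"]],
      coef(counts$best)[["dam_backgroundhatchery"]],
      coef(counts$best)[["log_eggs"]],
      smolt$percent_effect[["point"]],
      contrast$grand_means[["wild"]], contrast$grand_means[["hatchery"]]),
    stringsAsFactors = FALSE)
  status_tab <- table(factor(assignments$status,
                             levels = c("assigned", "unassigned", "ambiguous",
                                        "excluded_missingness")))
  write_stage(study$crosses, outdir, "crosses", seed)
  write_stage(study$broodstock, outdir, "broodstock", seed)
  write_stage(study$offspring, outdir, "offspring", seed)
  write_stage(as.data.frame(assignments), outdir, "assignments", seed)
  write_stage(family, outdir, "family_table", seed)
  write_stage(runs, outdir, "run_years", seed)
  write_stage(recov, outdir, "recovery", seed)
  if (!is.null(outdir)) {
    write_panel(panel, file.path(outdir, "panel.tsv"))
    write_genotypes(study$genotypes$offspring, file.path(outdir, "offspring_genotypes.tsv"))
    write_genotypes(study$genotypes$broodstock, file.path(outdir, "broodstock_genotypes.tsv"))
  }
  out <- list(config = config, panel = panel, study = study,
              ancestry = list(broodstock = anc_bs, offspring = anc_off),
              assignments = assignments, assignment_counts = status_tab,
              family = family, fits = list(counts = counts, eggs = eggs,
                                           smolt = smolt, contrast = contrast),
              recovery = recov, n_offspring_input = nrow(study$offspring))
  class(out) <- "study_report"
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("=== Synthetic stocking study report ===\n")
  cat(sprintf("seed %d; %d pairs, %d offspring simulated\n",
              x$config$seed, nrow(x$study$crosses), x$n_offspring_input))
  cat("\n-- parentage --\n")
  for (s in names(x$assignment_counts))
    cat(sprintf("  %-20s %d\n", s, x$assignment_counts[[s]]))
  cat(sprintf("  families recovered: %d\n", nrow(x$family)))
  cat("\n-- count models --\n")
  print(x$fits$counts$best)
  cat(sprintf("  AIC improvement from log egg number: %.2f\n", x$fits$counts$dAIC))
  cat("\n-- smolt length --\n")
  cat(sprintf("  percent effect of full introgression: %.2f (%.2f, %.2f)\n",
              x$fits$smolt$percent_effect[["point"]],
              x$fits$smolt$percent_effect[["lower"]],
              x$fits$smolt$percent_effect[["upper"]]))
  cat("\n-- run-year contrast --\n")
  print(x$fits$contrast)
  cat("\n-- truth vs estimate --\n")
  rec <- x$recovery
  rec$truth <- signif(rec$truth, 4); rec$estimate <- signif(rec$estimate, 4)
  print(rec, row.names = FALSE)
  invisible(x)
}
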