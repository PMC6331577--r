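test_that("offspring are Mendelian-consistent and matrilineal before error injection", {
  p <- simulate_panel(12, 4, 6, seed = 2, calibrate = FALSE)
  cfg <- effect_config(genotyping_error_rate = 0, missing_rate = 0)
  s <- simulate_crosses(cfg, n_pairs = 20, years = 2005:2007, seed = 3,
                        panel = p, genotypes = TRUE)
  g <- s$genotypes
  for (i in seq_len(nrow(s$offspring))) {
    mm <- count_mismatches(g$offspring[i, ],
                           g$broodstock[s$offspring$true_dam[i], ],
                           g$broodstock[s$offspring$true_sire[i], ])
    expect_identical(mm$mismatch_count, 0L)
    expect_identical(unname(g$offspring_mt[i, ]),
                     unname(g$broodstock_mt[s$offspring$true_dam[i], ]))
  }
  expect_true(all(s$crosses$n_offspring >= 1))
})

test_that("identical config and seed give identical studies", {
  p <- simulate_panel(8, 2, 3, seed = 1, calibrate = FALSE)
  a <- simulate_crosses(n_pairs = 15, seed = 42, panel = p, genotypes = TRUE)
  b <- simulate_crosses(n_pairs = 15, seed = 42, panel = p, genotypes = TRUE)
  expect_identical(a$crosses, b$crosses)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$offspring, b$offspring)
  r1 <- simulate_run_years(seed = 7)
  r2 <- simulate_run_years(seed = 7)
  expect_identical(r1, r2)
})

test_that("allele dosage matches its Monte-Carlo expectation at half ancestry", {
  # wild 0.1 / farmed 0.9 at every locus, true_d = 0.5: expected dosage
  # 2 * (0.5*0.9 + 0.5*0.1) = 1.0
  p <- toy_panel(n_diag = 20, w = 0.1, f = 0.9)
  set.seed(9)
  g <- simulate_genotypes(p, rep(0.5, 400))
  expect_equal(mean(g), 1.0, tolerance = 0.02)
})

test_that("ancestry limits are respected in single-individual simulation", {
  p <- toy_panel(n_diag = 15, w = 0.001, f = 0.999, n_mt = 5)
  farmed <- simulate_individual(p, 1, seed = 4)
  expect_true(all(farmed$genotypes == 2))
  wild <- simulate_individual(p, 0, seed = 4)
  expect_true(all(wild$genotypes == 0))
  expect_identical(farmed$true_d, 1)
  expect_error(simulate_individual(p, 1.2), "true_d")
})

test_that("default study reproduces the observed family-size scale", {
  s <- simulate_crosses(n_pairs = 850, years = 2005:2011, seed = 10)
  expect_equal(mean(s$crosses$n_offspring), 10.3, tolerance = 0.1)
  expect_gte(min(s$crosses$n_offspring), 1)
})

test_that("null effects with no year variance leave no introgression signal", {
  cfg <- effect_config(beta_intercept = 2.3, beta_dam_hatchery = 0,
                       beta_introgression_wild_dam = 0,
                       beta_introgression_hatchery_dam = 0,
                       beta_log_eggs = 0, sigma_year = 0)
  s <- simulate_crosses(cfg, n_pairs = 400, seed = 6)
  fit <- stats::lm(log(n_offspring) ~ true_pair_d, data = s$crosses)
  z <- summary(fit)$coefficients["true_pair_d", "t value"]
  expect_lt(abs(z), 3)
})

test_that("simulated growth is centred on the reported group smolt sizes", {
  h <- simulate_adults(n = 3000, origin = "hatchery", seed = 2)
  w <- simulate_adults(n = 3000, origin = "wild", seed = 2)
  expect_equal(mean(h$smolt_length), 232, tolerance = 0.02)
  expect_equal(mean(w$smolt_length), 152, tolerance = 0.02)
  expect_true(all(h$smolt_radius <= h$total_radius))
})

test_that("run-year generator honours its group means and degenerate limits", {
  r <- simulate_run_years(n_years = 40, n_per_group = 150, seed = 5)
  gm <- tapply(r$p_ind, r$origin, mean)
  # raw means sit slightly above the logit-scale centres (Jensen), wide check
  expect_equal(unname(gm[["wild"]]), 0.092, tolerance = 0.35)
  expect_equal(unname(gm[["hatchery"]]), 0.27, tolerance = 0.2)
  cfg0 <- effect_config(sigma_logit_year = 0, sigma_logit_ind = 0)
  r0 <- simulate_run_years(cfg0, n_years = 1, n_per_group = 10, seed = 1)
  expect_equal(length(unique(r0$p_ind[r0$origin == "wild"])), 1)
  expect_equal(length(unique(r0$p_ind[r0$origin == "hatchery"])), 1)
  cfg_eq <- effect_config(introgression_means = c(wild = 0.15, hatchery = 0.15))
  req <- simulate_run_years(cfg_eq, n_years = 10, n_per_group = 200, seed = 3)
  d <- tapply(req$p_ind, req$origin, mean)
  expect_equal(unname(d[["hatchery"]] - d[["wild"]]), 0, tolerance = 0.02)
})

test_that("malformed effect configurations are rejected", {
  expect_error(effect_config(sigma_resid = -1), "sigma_resid")
  expect_error(effect_config(genotyping_error_rate = 2), "genotyping_error_rate")
  expect_error(effect_config(introgression_means = c(wild = 0, hatchery = 0.3)),
               "introgression_means")
})
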