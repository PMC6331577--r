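# Small deterministic fixtures shared across test files.

# Panel with hand-set frequencies: n diagnostic nuclear loci at wild w /
# farmed f, plus optional neutral and mt loci.
toy_panel <- function(n_diag = 10, w = 0.1, f = 0.9, n_neutral = 0, n_mt = 0,
                      p_w = 0.0644, p_d = 0.903) {
  n <- n_diag + n_neutral + n_mt
  ref_panel(
    locus = c(sprintf("d%02d", seq_len(n_diag)),
              if (n_neutral) sprintf("n%02d", seq_len(n_neutral)),
              if (n_mt) sprintf("m%02d", seq_len(n_mt))),
    wild_freq = rep(w, n), farmed_freq = rep(f, n),
    diagnostic = c(rep(TRUE, n_diag), rep(FALSE, n_neutral), rep(FALSE, n_mt)),
    mt = c(rep(FALSE, n_diag + n_neutral), rep(TRUE, n_mt)),
    p_w = p_w, p_d = p_d)
}

# Dense grid-search oracle for the ancestry MLE (independent of optimise()).
grid_mle <- function(genotypes, panel, n_grid = 10001) {
  diag <- panel[panel$diagnostic & !panel$mt, ]
  g <- genotypes[diag$locus]
  keep <- !is.na(g)
  g <- as.numeric(g[keep])
  w <- pmin(pmax(diag$wild_freq[keep], 1e-4), 1 - 1e-4)
  f <- pmin(pmax(diag$farmed_freq[keep], 1e-4), 1 - 1e-4)
  qs <- seq(0, 1, length.out = n_grid)
  ll <- vapply(qs, function(q) {
    p <- pmin(pmax(q * f + (1 - q) * w, 1e-12), 1 - 1e-12)
    sum(g * log(p) + (2 - g) * log(1 - p))
  }, 0)
  qs[which.max(ll)]
}

# Brute-force Mendelian mismatch oracle: enumerate the 4 ordered transmission
# combinations per locus.
brute_mismatches <- function(off, dam, sire) {
  alleles <- function(g) switch(as.character(g), "0" = c(0, 0), "1" = c(0, 1),
                                "2" = c(1, 1))
  mm <- 0L; nc <- 0L
  for (l in seq_along(off)) {
    if (is.na(off[l]) || is.na(dam[l]) || is.na(sire[l])) next
    nc <- nc + 1L
    possible <- FALSE
    for (ad in alleles(dam[l])) for (as_ in alleles(sire[l]))
      if (ad + as_ == off[l]) possible <- TRUE
    if (!possible) mm <- mm + 1L
  }
  list(mismatch_count = mm, loci_compared = nc)
}

# Family table directly from generator truth (no genotyping/assignment step);
# used by recovery tests that exercise the models, not parentage.
truth_family_table <- function(study) {
  cr <- study$crosses
  data.frame(dam = cr$dam, sire = cr$sire, brood_year = cr$brood_year,
             n_offspring = cr$n_offspring, dam_background = cr$dam_background,
             sire_background = cr$sire_background,
             pair_introgression = cr$true_pair_d,
             egg_size = cr$egg_size, egg_number = cr$egg_number,
             dam_weight = cr$dam_weight, stringsAsFactors = FALSE)
}

truth_dam_table <- function(study) {
  cr <- study$crosses
  data.frame(egg_size = cr$egg_size, egg_number = cr$egg_number,
             dam_weight = cr$dam_weight, dam_background = cr$dam_background,
             introgression = cr$true_d_dam, brood_year = cr$brood_year,
             stringsAsFactors = FALSE)
}

growth_table <- function(adults) {
  adults$introgression <- adults$true_d
  adults$brood_year <- adults$birth_year
  adults
}

# Gauss-Hermite nodes/weights by Golub-Welsch, for the quadrature oracle of
# the sea-age marginal likelihood.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}
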