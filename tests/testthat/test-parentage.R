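test_that("single-locus transmission logic is correct", {
  expect_equal(count_mismatches(2L, 0L, 0L)$mismatch_count, 1)
  expect_equal(count_mismatches(0L, 2L, 0L)$mismatch_count, 1)
  for (o in 0:2)  # heterozygous parents permit every offspring genotype
    expect_equal(count_mismatches(o, 1L, 1L)$mismatch_count, 0)
  expect_equal(count_mismatches(NA_integer_, 1L, 1L)$loci_compared, 0)
  expect_error(count_mismatches(c(0L, 1L), 0L, 0L), "equal length")
})

test_that("mismatch counting equals the brute-force transmission oracle", {
  set.seed(14)
  for (rep in 1:300) {
    L <- sample(3:12, 1)
    trio <- lapply(1:3, function(i) {
      g <- sample(0:2, L, replace = TRUE)
      g[stats::runif(L) < 0.15] <- NA
      as.integer(g)
    })
    got <- count_mismatches(trio[[1]], trio[[2]], trio[[3]])
    want <- brute_mismatches(trio[[1]], trio[[2]], trio[[3]])
    expect_identical(got$mismatch_count, want$mismatch_count)
    expect_identical(got$loci_compared, want$loci_compared)
  }
})

test_that("an engineered 81-locus trio scores exactly its impossible loci", {
  dam <- rep(1L, 81); sire <- rep(1L, 81)
  off <- rep(1L, 81)
  dam[5] <- 0L; sire[5] <- 0L; off[5] <- 2L
  dam[50] <- 2L; sire[50] <- 2L; off[50] <- 0L
  got <- count_mismatches(off, dam, sire)
  expect_equal(got$mismatch_count, 2)
  expect_equal(got$loci_compared, 81)
})

test_that("maternity verification is a faithful tri-state", {
  h <- as.integer(c(1, 0, 1, 1, 0))
  expect_equal(verify_maternity(h, h), "consistent")
  h2 <- h; h2[3] <- 0L
  expect_equal(verify_maternity(h2, h), "inconsistent")
  expect_equal(verify_maternity(rep(NA_integer_, 5), h), "untestable")
  hm <- h; hm[2:3] <- NA
  expect_equal(verify_maternity(hm, h), "consistent")
})

test_that("perfect data is assigned to the true parents without error", {
  p <- simulate_panel(seed = 4)
  cfg <- effect_config(genotyping_error_rate = 0, missing_rate = 0)
  s <- simulate_crosses(cfg, n_pairs = 85, seed = 17, panel = p, genotypes = TRUE)
  n <- min(nrow(s$offspring), 500)
  idx <- seq_len(n)
  asg <- assign_parentage(s$genotypes$offspring[idx, ], s$offspring$brood_year[idx],
                          s$broodstock, s$genotypes$broodstock,
                          s$genotypes$offspring_mt[idx, ], s$genotypes$broodstock_mt)
  expect_true(all(asg$status == "assigned"))
  expect_true(all(asg$mismatch_count == 0))
  expect_identical(asg$dam, s$offspring$true_dam[idx])
  expect_identical(asg$sire, s$offspring$true_sire[idx])
  expect_true(all(asg$mt_consistent == "consistent"))
  fam <- build_family_table(asg, s$broodstock, s$crosses)
  truth_counts <- table(s$offspring$pair_id[idx])
  expect_equal(sum(fam$n_offspring), n)
  m <- match(paste(s$crosses$dam, s$crosses$sire), paste(fam$dam, fam$sire))
  got <- ifelse(is.na(m), 0L, fam$n_offspring[m])
  want <- as.integer(truth_counts[s$crosses$pair_id])
  want[is.na(want)] <- 0L
  expect_equal(got, want, ignore_attr = TRUE)
  expect_equal(fam$pair_introgression,
               (s$broodstock$true_d[match(fam$dam, s$broodstock$id)] +
                  s$broodstock$true_d[match(fam$sire, s$broodstock$id)]) / 2)
})

test_that("realistic genotyping error still recovers nearly all families", {
  p <- simulate_panel(seed = 4)
  s <- simulate_crosses(n_pairs = 85, seed = 23, panel = p, genotypes = TRUE)
  asg <- assign_parentage(s$genotypes$offspring, s$offspring$brood_year,
                          s$broodstock, s$genotypes$broodstock)
  correct <- asg$status == "assigned" &
    asg$dam == s$offspring$true_dam & asg$sire == s$offspring$true_sire &
    asg$mismatch_count <= 2
  expect_gte(mean(correct, na.rm = TRUE), 0.99)
  expect_true(all(asg$mismatch_count[asg$status == "assigned"] <= 2))
})

test_that("heavy missingness and ties are statuses, not errors", {
  p <- toy_panel(n_diag = 20, w = 0.05, f = 0.95, n_neutral = 61)
  set.seed(5)
  dam_g <- simulate_genotypes(p, 0.1)[1, ]
  sire_g <- simulate_genotypes(p, 0.1)[1, ]
  off <- mapply(function(d, s) {
    td <- if (d == 1) sample(0:1, 1) else d / 2
    ts <- if (s == 1) sample(0:1, 1) else s / 2
    td + ts
  }, dam_g, sire_g)
  off <- as.integer(off)
  roster <- data.frame(id = c("d1", "d2", "s1"), sex = c("F", "F", "M"),
                       brood_year = 2005L, stringsAsFactors = FALSE)
  G <- rbind(d1 = dam_g, d2 = dam_g, s1 = sire_g)  # duplicate dam forces a tie
  om <- matrix(off, 1, dimnames = list("o1", names(dam_g)))
  tie <- assign_parentage(om, 2005L, roster, G)
  expect_equal(tie$status, "ambiguous")
  # > 20% missing nuclear genotypes is excluded before scoring
  om_miss <- om
  om_miss[1, 1:17] <- NA
  ex <- assign_parentage(om_miss, 2005L, roster, G)
  expect_equal(ex$status, "excluded_missingness")
  # unique parents, no tie
  uniq <- assign_parentage(om, 2005L, roster[-2, ], G[-2, ])
  expect_equal(uniq$status, "assigned")
  expect_equal(uniq$dam, "d1")
  # a pair outside the brood-year window is not considered
  far <- roster; far$brood_year <- 2010L
  out <- assign_parentage(om, 2005L, far, G)
  expect_equal(out$status, "unassigned")
})

test_that("family aggregation handles edge cases", {
  empty <- structure(data.frame(id = "x", status = "unassigned", dam = NA,
                                sire = NA, mismatch_count = NA,
                                loci_compared = NA, n_pairs_evaluated = 0L,
                                mt_consistent = NA,
                                assigned_brood_year = NA,
                                stringsAsFactors = FALSE),
                     class = c("assignment_table", "data.frame"))
  expect_equal(nrow(build_family_table(empty,
                                       data.frame(id = character(0)))), 0)
})
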