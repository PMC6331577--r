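test_that("the ancestry MLE hits the boundaries and symmetry points", {
  p <- toy_panel(n_diag = 12, w = 0.01, f = 0.99)
  g <- stats::setNames(rep(2L, 12), p$locus)
  expect_gt(estimate_p_ind(g, p)$p_ind, 0.999)
  g0 <- stats::setNames(rep(0L, 12), p$locus)
  expect_lt(estimate_p_ind(g0, p)$p_ind, 0.001)
  # mirrored panel with fully heterozygous genotypes: exact symmetry at 0.5
  pm <- ref_panel(sprintf("l%02d", 1:10),
                  wild_freq = c(rep(0.9, 5), rep(0.1, 5)),
                  farmed_freq = c(rep(0.1, 5), rep(0.9, 5)),
                  diagnostic = rep(TRUE, 10), mt = rep(FALSE, 10))
  gh <- stats::setNames(rep(1L, 10), pm$locus)
  expect_equal(estimate_p_ind(gh, pm)$p_ind, 0.5, tolerance = 1e-6)
})

test_that("the MLE agrees with a dense grid-search oracle", {
  set.seed(21)
  p <- simulate_panel(10, 0, 0, divergence = 0.5, seed = 8, calibrate = FALSE)
  for (td in c(0.05, 0.3, 0.5, 0.8)) {
    g <- simulate_genotypes(p, td)[1, ]
    g[sample(10, 2)] <- NA  # missing loci are skipped
    est <- estimate_p_ind(g, p)
    expect_lt(abs(est$p_ind - grid_mle(g, p)), 1e-4)
    expect_equal(est$n_loci_used, 8L)
  }
})

test_that("the ancestry rescaling is the exact affine formula", {
  p <- toy_panel(1)  # carries the published constants 0.0644 / 0.903
  expect_equal(compute_D(0.903, p), 1.0)
  expect_equal(compute_D(0.0644, p), 0.0)
  expect_equal(compute_D(0.48, p), (0.48 - 0.0644) / (0.903 - 0.0644))
  expect_equal(compute_D(0.48, p), 0.4956, tolerance = 1e-4)
  # affine and strictly increasing; raw values may leave [0,1]
  x <- seq(0, 1, 0.1)
  d <- compute_D(x, p)
  expect_true(all(diff(d) > 0))
  expect_equal(diff(d), rep(0.1 / (0.903 - 0.0644), 10))
  expect_gt(compute_D(1, p), 1)
  expect_equal(compute_D(1, p, clamp = TRUE), 1)
  expect_error(compute_D(0.5, p_w = 0.3, p_d = 0.3), "undefined")
})

test_that("unestimable and malformed inputs are explicit, not silent", {
  p <- toy_panel(5, n_neutral = 2)
  g <- stats::setNames(rep(NA_integer_, 7), p$locus)
  est <- estimate_p_ind(g, p)
  expect_false(est$estimable)
  expect_true(is.na(est$p_ind))
  m <- rbind(a = c(1L, 1L, 1L, 1L, 1L, 0L, 0L),
             b = rep(NA_integer_, 7))
  colnames(m) <- p$locus
  be <- batch_estimate(m, p)
  expect_equal(be$id, c("a", "b"))
  expect_true(be$estimable[1])
  expect_false(be$estimable[2])
  bad <- m; colnames(bad)[1] <- "nope"
  expect_error(batch_estimate(bad, p), "nope")
  empty <- batch_estimate(m[0, , drop = FALSE], p)
  expect_equal(nrow(empty), 0)
})

test_that("only diagnostic loci enter the likelihood", {
  p <- toy_panel(6, w = 0.2, f = 0.8, n_neutral = 4)
  set.seed(3)
  g <- simulate_genotypes(p, 0.4)[1, ]
  full <- estimate_p_ind(g, p)
  g_flip <- g
  neutral <- p$locus[!p$diagnostic]
  g_flip[neutral] <- 2L - g_flip[neutral]
  expect_equal(estimate_p_ind(g_flip, p)$p_ind, full$p_ind)
  expect_equal(estimate_p_ind(g[p$locus[p$diagnostic]], p)$p_ind, full$p_ind)
})

test_that("rescaled estimates track the generating ancestry one-to-one", {
  p <- simulate_panel(seed = 31)
  set.seed(31)
  true_d <- stats::runif(500)
  g <- simulate_genotypes(p, true_d)
  est <- batch_estimate(g, p)
  expect_true(all(est$estimable))
  expect_equal(mean(est$d - true_d), 0, tolerance = 0.02)
  slope <- stats::coef(stats::lm(est$d ~ true_d))[["true_d"]]
  expect_gte(slope, 0.9)
  expect_lte(slope, 1.1)
})
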