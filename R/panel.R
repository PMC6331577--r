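#' Reference allele-frequency panel
#'
#' A panel holds, for each locus, the allele frequency of the counted allele in
#' the wild and farmed reference populations, a flag for the diagnostic loci
#' (large wild/farmed differentiation; the only loci that enter ancestry
#' estimation) and a flag for mitochondrial loci (haploid; used for maternity
#' verification only). The panel also carries the two scaling constants used to
#' rescale a membership probability to proportion farmed ancestry: the mean
#' membership probability of a pure wild reference sample (`p_w`) and of farmed
#' reference samples (`p_d`). Defaults are the published reference values
#' 0.0644 and 0.903.
#'
#' @param locus character vector of locus ids.
#' @param wild_freq,farmed_freq numeric allele frequencies in (0,1).
#' @param diagnostic logical flag per locus.
#' @param mt logical flag per locus (mitochondrial, haploid).
#' @param p_w,p_d scaling constants on the probability scale; `p_d > p_w`.
#' @return An object of class `ref_panel` (a data frame with one row per locus
#'   and attributes `p_w`, `p_d`).
#' @export
ref_panel <- function(locus, wild_freq, farmed_freq, diagnostic, mt,
                      p_w = 0.0644, p_d = 0.903) {
  n <- length(locus)
  stop_if(length(wild_freq) != n || length(farmed_freq) != n ||
            length(diagnostic) != n || length(mt) != n,
          "all per-locus vectors must have the same length")
  check_prob(wild_freq, "wild_freq", open = TRUE)
  check_prob(farmed_freq, "farmed_freq", open = TRUE)
  stop_if(!is.numeric(p_w) || !is.numeric(p_d) || p_d <= p_w,
          "scaling constants must satisfy p_d > p_w")
  out <- data.frame(locus = as.character(locus), wild_freq = wild_freq,
                    farmed_freq = farmed_freq, diagnostic = as.logical(diagnostic),
                    mt = as.logical(mt), stringsAsFactors = FALSE)
  attr(out, "p_w") <- p_w
  attr(out, "p_d") <- p_d
  class(out) <- c("ref_panel", "data.frame")
  out
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d nuclear loci (%d diagnostic) + %d mtDNA loci\n",
              sum(!x$mt), sum(x$diagnostic & !x$mt), sum(x$mt)))
  cat(sprintf("Scaling constants: P_W = %.4f, P_D = %.4f\n",
              attr(x, "p_w"), attr(x, "p_d")))
  invisible(x)
}

#' Simulate a diagnostic SNP reference panel
#'
#' Draws wild and farmed reference allele frequencies for a panel laid out like
#' the study panel: `n_diagnostic` differentiated nuclear loci, `n_neutral`
#' undifferentiated nuclear loci and `n_mt` mitochondrial loci. At diagnostic
#' loci the absolute wild/farmed frequency difference is controlled by
#' `divergence`; at neutral loci the two references share a common frequency up
#' to small jitter.
#'
#' When `calibrate = TRUE` the panel's scaling constants are set by Monte
#' Carlo: the mean maximum-likelihood ancestry estimate over simulated pure
#' wild (true ancestry 0) and pure farmed (true ancestry 1) genomes. This
#' mirrors how the constants are obtained from reference samples in practice
#' (neither is exactly 0 or 1 for a finite panel) and makes the rescaled
#' ancestry comparable with its generating value.
#'
#' @param n_diagnostic,n_neutral,n_mt locus counts (defaults 48, 33, 15).
#' @param divergence scalar in \[0,1): expected wild/farmed frequency
#'   separation at diagnostic loci; 0 gives identical references.
#' @param seed integer seed; the same spec and seed reproduce the panel.
#' @param calibrate logical; calibrate `p_w`/`p_d` by simulation (see Details).
#' @param n_ref reference sample size per population used for calibration.
#' @return A [ref_panel()].
#' @export
simulate_panel <- function(n_diagnostic = 48, n_neutral = 33, n_mt = 15,
                           divergence = 0.6, seed = 1, calibrate = TRUE,
                           n_ref = 150) {
  stop_if(n_diagnostic < 0 || n_neutral < 0 || n_mt < 0, "locus counts must be >= 0")
  stop_if(!is.numeric(divergence) || length(divergence) != 1 ||
            is.na(divergence) || divergence < 0 || divergence >= 1,
          "'divergence' must be a scalar in [0, 1)")
  with_substream(seed, "panel", {
    n_nuc <- n_diagnostic + n_neutral
    ## diagnostic: separation |wild - farmed| close to `divergence`, random
    ## orientation; neutral: shared frequency with jitter shrinking to 0 with
    ## divergence 0; mt: moderately differentiated haploid loci.
    delta <- divergence * runif(n_diagnostic, 0.85, 1)
    centre <- runif(n_diagnostic, 0.02 + delta / 2, 0.98 - delta / 2)
    sgn <- sample(c(-1, 1), n_diagnostic, replace = TRUE)
    wild_d <- centre - sgn * delta / 2
    farm_d <- centre + sgn * delta / 2
    base_n <- runif(n_neutral, 0.05, 0.95)
    jit <- divergence * 0.02
    wild_n <- pmin(pmax(base_n + rnorm(n_neutral, 0, jit + 1e-12), 0.01), 0.99)
    farm_n <- if (divergence == 0) wild_n else
      pmin(pmax(base_n + rnorm(n_neutral, 0, jit), 0.01), 0.99)
    if (divergence == 0) { wild_n <- base_n; farm_n <- base_n }
    dmt <- divergence * 0.5 * runif(n_mt, 0.5, 1)
    cmt <- runif(n_mt, 0.05 + dmt / 2, 0.95 - dmt / 2)
    smt <- sample(c(-1, 1), n_mt, replace = TRUE)
    panel <- ref_panel(
      locus = c(sprintf("snp%03d", seq_len(n_nuc)),
                if (n_mt) sprintf("mt%02d", seq_len(n_mt))),
      wild_freq = c(wild_d, wild_n, cmt - smt * dmt / 2),
      farmed_freq = c(farm_d, farm_n, cmt + smt * dmt / 2),
      diagnostic = c(rep(TRUE, n_diagnostic), rep(FALSE, n_neutral), rep(FALSE, n_mt)),
      mt = c(rep(FALSE, n_nuc), rep(TRUE, n_mt)))
    if (calibrate && n_diagnostic > 0) {
      qhat <- function(true_d) {
        g <- simulate_genotypes(panel, rep(true_d, n_ref))
        mean(batch_estimate(g, panel)$p_ind)
      }
      p_w <- qhat(0); p_d <- qhat(1)
      if (p_d > p_w) { attr(panel, "p_w") <- p_w; attr(panel, "p_d") <- p_d }
    }
    panel
  })
}

#' Write / read a reference panel as tab-separated text
#'
#' The header line carries the scaling constants as `# p_w=<x> p_d=<y>`.
#' @param panel a [ref_panel()].
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# p_w=%.10g p_d=%.10g", attr(panel, "p_w"), attr(panel, "p_d")), con)
  utils::write.table(panel, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("p_w=([0-9.eE+-]+) p_d=([0-9.eE+-]+)", hdr))[[1]]
  stop_if(length(m) != 3, "panel file lacks the scaling-constant header")
  d <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                         stringsAsFactors = FALSE)
  ref_panel(d$locus, d$wild_freq, d$farmed_freq, d$diagnostic, d$mt,
            p_w = as.numeric(m[2]), p_d = as.numeric(m[3]))
}
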