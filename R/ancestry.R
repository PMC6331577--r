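#' Maximum-likelihood farmed-membership probability for one individual
#'
#' Estimates the admixture proportion `q` maximizing the binomial
#' log-likelihood over the panel's non-missing diagnostic loci,
#' \deqn{\ell(q) = \sum_l g_l \ln p_l(q) + (2 - g_l) \ln(1 - p_l(q)),}
#' with mixture frequency \eqn{p_l(q) = q f_l + (1-q) w_l} (farmed and wild
#' reference frequencies). Reference frequencies are truncated to
#' \[1e-4, 1-1e-4\] before evaluation. The maximizer on \[0,1\] is found by
#' bracketed scalar optimization to tolerance 1e-8, with the endpoints checked
#' explicitly; a curvature-based standard error is reported for interior
#' optima.
#'
#' @param genotypes named integer vector of 0/1/2 calls (NA = missing); names
#'   must match panel locus ids. Only diagnostic nuclear loci are used.
#' @param panel a [ref_panel()].
#' @param id optional individual id carried into the result.
#' @return An object of class `ancestry_est`: a one-row data frame with
#'   `id`, `p_ind`, `d` (rescaled proportion farmed ancestry), `se_p_ind`,
#'   `n_loci_used` and `estimable`.
#' @seealso [compute_D()], [batch_estimate()]
#' @export
estimate_p_ind <- function(genotypes, panel, id = NA_character_) {
  diag <- panel[panel$diagnostic & !panel$mt, ]
  stop_if(nrow(diag) == 0, "panel has no diagnostic loci")
  g <- genotypes[diag$locus]
  keep <- !is.na(g)
  if (!any(keep)) {
    out <- data.frame(id = id, p_ind = NA_real_, d = NA_real_,
                      se_p_ind = NA_real_, n_loci_used = 0L, estimable = FALSE,
                      stringsAsFactors = FALSE)
    class(out) <- c("ancestry_est", "data.frame")
    return(out)
  }
  g <- as.numeric(g[keep])
  stop_if(any(!g %in% 0:2), "genotype calls must be 0, 1, 2 or NA")
  w <- pmin(pmax(diag$wild_freq[keep], 1e-4), 1 - 1e-4)
  f <- pmin(pmax(diag$farmed_freq[keep], 1e-4), 1 - 1e-4)
  delta <- f - w
  ll <- function(q) {
    p <- q * f + (1 - q) * w
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(g * log(p) + (2 - g) * log(1 - p))
  }
  opt <- stats::optimise(ll, c(0, 1), maximum = TRUE, tol = 1e-9)
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, ll(0), ll(1))
  qhat <- cand[which.max(vals)]
  ## curvature-based SE at the optimum
  p <- qhat * f + (1 - qhat) * w
  info <- sum(delta^2 * (g / p^2 + (2 - g) / (1 - p)^2))
  se <- if (info > 0) 1 / sqrt(info) else NA_real_
  out <- data.frame(id = id, p_ind = qhat, d = compute_D(qhat, panel),
                    se_p_ind = se, n_loci_used = sum(keep), estimable = TRUE,
                    stringsAsFactors = FALSE)
  class(out) <- c("ancestry_est", "data.frame")
  out
}

#' Rescale a membership probability to proportion farmed ancestry
#'
#' Applies the affine rescaling \eqn{D = (P_{ind} - P_W) / (P_D - P_W)} using
#' the panel's scaling constants (or explicitly supplied ones). Because the
#' farmed reference mean is below one and the wild reference mean above zero,
#' raw `D` can fall outside \[0,1\]; no clamping is applied unless requested.
#' Statistical models use the raw value.
#'
#' @param p_ind membership probability (vectorized).
#' @param panel a [ref_panel()] carrying `p_w`/`p_d`; or supply them directly.
#' @param p_w,p_d scaling constants; `p_d` must differ from `p_w`.
#' @param clamp clamp the result into \[0,1\]?
#' @return numeric vector of proportion farmed ancestry.
#' @export
compute_D <- function(p_ind, panel = NULL, p_w = NULL, p_d = NULL, clamp = FALSE) {
  if (!is.null(panel)) {
    p_w <- p_w %||% attr(panel, "p_w")
    p_d <- p_d %||% attr(panel, "p_d")
  }
  stop_if(is.null(p_w) || is.null(p_d), "scaling constants p_w and p_d are required")
  stop_if(p_d == p_w, "undefined rescaling: p_d equals p_w")
  d <- (p_ind - p_w) / (p_d - p_w)
  if (clamp) d <- pmin(pmax(d, 0), 1)
  d
}

#' Estimate ancestry for a genotype matrix
#'
#' One estimate per row of `genotypes`; rows whose diagnostic loci are all
#' missing are flagged unestimable rather than failing the batch.
#'
#' @param genotypes integer matrix (individuals x nuclear loci), 0/1/2/NA,
#'   with column names matching panel locus ids.
#' @param panel a [ref_panel()].
#' @return An `ancestry_est` data frame, one row per individual, in input
#'   order.
#' @export
batch_estimate <- function(genotypes, panel) {
  stop_if(!is.matrix(genotypes), "'genotypes' must be a matrix")
  if (nrow(genotypes) == 0) {
    out <- data.frame(id = character(0), p_ind = numeric(0), d = numeric(0),
                      se_p_ind = numeric(0), n_loci_used = integer(0),
                      estimable = logical(0), stringsAsFactors = FALSE)
    class(out) <- c("ancestry_est", "data.frame")
    return(out)
  }
  nuc <- panel$locus[!panel$mt]
  unknown <- setdiff(colnames(genotypes), panel$locus)
  stop_if(length(unknown) > 0,
          "genotype columns not in panel: ", paste(unknown, collapse = ", "))
  missing_diag <- setdiff(panel$locus[panel$diagnostic & !panel$mt],
                          colnames(genotypes))
  stop_if(length(missing_diag) > 0,
          "diagnostic loci absent from genotypes: ",
          paste(missing_diag, collapse = ", "))
  ids <- rownames(genotypes) %||% sprintf("ind%04d", seq_len(nrow(genotypes)))
  res <- lapply(seq_len(nrow(genotypes)), function(i)
    estimate_p_ind(genotypes[i, ], panel, id = ids[i]))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("ancestry_est", "data.frame")
  out
}

#' @export
print.ancestry_est <- function(x, ...) {
  cat(sprintf("Ancestry estimates for %d individual(s); %d unestimable\n",
              nrow(x), sum(!x$estimable)))
  if (nrow(x) > 0 && any(x$estimable))
    cat(sprintf("  mean P_ind = %.3f, mean D = %.3f (n loci used: %s)\n",
                mean(x$p_ind, na.rm = TRUE), mean(x$d, na.rm = TRUE),
                paste(range(x$n_loci_used[x$estimable]), collapse = "-")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Read/write genotype matrices as tab-separated text
#'
#' Rows are individuals, columns loci, calls 0/1/2 with missing written as NA.
#' @param genotypes integer matrix.
#' @param path file path.
#' @export
write_genotypes <- function(genotypes, path) {
  utils::write.table(cbind(id = rownames(genotypes), as.data.frame(genotypes)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- d$id
  m
}
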