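## Per-genotype transmissible-allele bounds: a parent with dosage 0 transmits
## 0 copies of the counted allele, dosage 2 transmits 1, a heterozygote either.
## An offspring dosage is Mendelian-possible for a pair iff it lies within the
## sum of the two parental bounds.
transmit_bounds <- function(g) {
  list(lo = as.integer(!is.na(g) & g == 2L), hi = as.integer(!is.na(g) & g >= 1L))
}

#' Count Mendelian mismatches for one offspring-dam-sire trio
#'
#' A locus is a mismatch iff no ordered pair of transmitted alleles (one from
#' each parent) can produce the offspring genotype. Loci with a missing call in
#' any of the three individuals are skipped and not counted in
#' `loci_compared`.
#'
#' @param offspring,dam,sire integer 0/1/2/NA vectors over the same locus set.
#' @return list with `mismatch_count` and `loci_compared`.
#' @export
count_mismatches <- function(offspring, dam, sire) {
  stop_if(length(offspring) != length(dam) || length(dam) != length(sire),
          "genotype vectors must have equal length")
  ok <- !is.na(offspring) & !is.na(dam) & !is.na(sire)
  o <- offspring[ok]
  bd <- transmit_bounds(dam[ok]); bs <- transmit_bounds(sire[ok])
  lo <- bd$lo + bs$lo; hi <- bd$hi + bs$hi
  list(mismatch_count = sum(o < lo | o > hi), loci_compared = sum(ok))
}

#' Verify maternity through the mitochondrial haplotype
#'
#' @param offspring_mt,dam_mt 0/1/NA haplotype vectors over the same mt loci.
#' @return `"consistent"` if all jointly non-missing loci agree,
#'   `"inconsistent"` if any disagrees, `"untestable"` if none are jointly
#'   non-missing.
#' @export
verify_maternity <- function(offspring_mt, dam_mt) {
  stop_if(length(offspring_mt) != length(dam_mt),
          "haplotype vectors must have equal length")
  ok <- !is.na(offspring_mt) & !is.na(dam_mt)
  if (!any(ok)) return("untestable")
  if (all(offspring_mt[ok] == dam_mt[ok])) "consistent" else "inconsistent"
}

## Mismatch and comparable-locus counts for one offspring against every
## dam x sire combination, via cross-products over locus subsets split by the
## offspring genotype value:
##   o = 0: mismatch iff either parent must transmit the allele  (lo_d + lo_s >= 1)
##   o = 2: mismatch iff either parent cannot transmit it        (hi_d + hi_s <= 1)
##   o = 1: mismatch iff both must (lo sum 2) or neither can (hi sum 0)
score_pairs <- function(off, dam_g, sire_g) {
  vo <- !is.na(off)
  vd <- !is.na(dam_g); vs <- !is.na(sire_g)
  lod <- (!is.na(dam_g) & dam_g == 2L) * 1; hid <- (!is.na(dam_g) & dam_g >= 1L) * 1
  los <- (!is.na(sire_g) & sire_g == 2L) * 1; his <- (!is.na(sire_g) & sire_g >= 1L) * 1
  n_d <- nrow(dam_g); n_s <- nrow(sire_g)
  mm <- matrix(0, n_d, n_s); nc <- matrix(0, n_d, n_s)
  xp <- function(A, B, cols) {
    if (!length(cols)) return(matrix(0, n_d, n_s))
    A[, cols, drop = FALSE] %*% t(B[, cols, drop = FALSE])
  }
  for (val in 0:2) {
    cols <- which(vo & off == val)
    if (!length(cols)) next
    ncmp <- xp(vd * 1, vs * 1, cols)
    nc <- nc + ncmp
    mm <- mm + switch(as.character(val),
      "0" = ncmp - xp((1 - lod) * vd, (1 - los) * vs, cols),
      "2" = ncmp - xp(hid * vd, his * vs, cols),
      "1" = xp(lod * vd, los * vs, cols) + xp((1 - hid) * vd, (1 - his) * vs, cols))
  }
  list(mismatches = mm, compared = nc)
}

#' Assign recaptured adults to broodstock pairs by Mendelian exclusion
#'
#' For each offspring: (1) offspring with more than `missing_threshold`
#' missing nuclear genotypes are excluded; (2) every dam x sire pair whose
#' brood years fall within the offspring's assigned brood year +/-
#' `year_window` is scored by Mendelian mismatch count; (3) the pair with the
#' minimum count is accepted if it is unique and within `max_mismatch`;
#' equal-minimum ties are reported as ambiguous and larger minima as
#' unassigned. Maternity of accepted pairs is verified against the dam's
#' mitochondrial haplotype when haplotypes are supplied.
#'
#' @param offspring_genotypes integer matrix (offspring x nuclear loci).
#' @param offspring_years integer vector of assigned brood years per offspring.
#' @param roster data frame of broodstock with columns `id`, `sex` ("F"/"M")
#'   and `brood_year`.
#' @param broodstock_genotypes integer matrix (broodstock x nuclear loci),
#'   rows named by roster id.
#' @param offspring_mt,broodstock_mt optional mtDNA haplotype matrices for
#'   maternity verification.
#' @param max_mismatch maximum accepted mismatch count (default 2).
#' @param missing_threshold maximum tolerated missing fraction (default 0.20).
#' @param year_window brood-year window half-width (default 1).
#' @return An object of class `assignment_table`: one row per offspring with
#'   `status` (assigned / unassigned / ambiguous / excluded_missingness),
#'   `dam`, `sire`, `mismatch_count`, `loci_compared`, `n_pairs_evaluated`,
#'   `mt_consistent` and `assigned_brood_year`.
#' @export
assign_parentage <- function(offspring_genotypes, offspring_years, roster,
                             broodstock_genotypes,
                             offspring_mt = NULL, broodstock_mt = NULL,
                             max_mismatch = 2, missing_threshold = 0.20,
                             year_window = 1) {
  stop_if(max_mismatch < 0, "'max_mismatch' must be >= 0")
  stop_if(nrow(offspring_genotypes) != length(offspring_years),
          "one brood year per offspring is required")
  stop_if(!all(c("id", "sex", "brood_year") %in% names(roster)),
          "roster needs columns id, sex, brood_year")
  stop_if(!all(roster$id %in% rownames(broodstock_genotypes)),
          "every roster id needs a genotype row")
  n <- nrow(offspring_genotypes)
  res <- data.frame(id = rownames(offspring_genotypes) %||% sprintf("off%04d", seq_len(n)),
                    status = NA_character_, dam = NA_character_, sire = NA_character_,
                    mismatch_count = NA_integer_, loci_compared = NA_integer_,
                    n_pairs_evaluated = 0L, mt_consistent = NA_character_,
                    assigned_brood_year = NA_integer_, stringsAsFactors = FALSE)
  L <- ncol(offspring_genotypes)
  for (i in seq_len(n)) {
    off <- offspring_genotypes[i, ]
    if (mean(is.na(off)) > missing_threshold) {
      res$status[i] <- "excluded_missingness"
      next
    }
    win <- roster$brood_year >= offspring_years[i] - year_window &
      roster$brood_year <= offspring_years[i] + year_window
    dams <- roster[win & roster$sex == "F", ]
    sires <- roster[win & roster$sex == "M", ]
    if (nrow(dams) == 0 || nrow(sires) == 0) {
      res$status[i] <- "unassigned"
      next
    }
    sc <- score_pairs(off, broodstock_genotypes[dams$id, , drop = FALSE],
                      broodstock_genotypes[sires$id, , drop = FALSE])
    res$n_pairs_evaluated[i] <- nrow(dams) * nrow(sires)
    mn <- min(sc$mismatches)
    hits <- which(sc$mismatches == mn, arr.ind = TRUE)
    if (mn > max_mismatch) {
      res$status[i] <- "unassigned"
    } else if (nrow(hits) > 1) {
      res$status[i] <- "ambiguous"
      res$mismatch_count[i] <- mn
    } else {
      dam_id <- dams$id[hits[1, 1]]; sire_id <- sires$id[hits[1, 2]]
      res$status[i] <- "assigned"
      res$dam[i] <- dam_id; res$sire[i] <- sire_id
      res$mismatch_count[i] <- mn
      res$loci_compared[i] <- sc$compared[hits[1, 1], hits[1, 2]]
      res$assigned_brood_year[i] <- dams$brood_year[hits[1, 1]]
      if (!is.null(offspring_mt) && !is.null(broodstock_mt) &&
          dam_id %in% rownames(broodstock_mt)) {
        res$mt_consistent[i] <- verify_maternity(offspring_mt[i, ],
                                                 broodstock_mt[dam_id, ])
      }
    }
  }
  class(res) <- c("assignment_table", "data.frame")
  res
}

#' @export
print.assignment_table <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("assigned", "unassigned", "ambiguous",
                                           "excluded_missingness")))
  cat(sprintf("Parentage assignment of %d offspring:\n", nrow(x)))
  for (s in names(tab)) cat(sprintf("  %-20s %d\n", s, tab[[s]]))
  if (tab[["assigned"]] > 0) {
    mm <- table(x$mismatch_count[x$status == "assigned"])
    cat("  mismatch counts among assigned:",
        paste(sprintf("%s:%d", names(mm), mm), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Aggregate assignments into a family (broodstock-pair) table
#'
#' One row per dam-sire pair with at least one assigned offspring; the pair's
#' introgression is the dam-sire mean of the supplied per-individual ancestry
#' values, and egg metrics are joined from the cross records when available.
#'
#' @param assignments an `assignment_table`.
#' @param broodstock roster data frame with `id`, `brood_year`, `background`
#'   and an ancestry column named by `d_col`.
#' @param crosses optional cross records with `dam`, `sire`, `egg_size`,
#'   `egg_number`, `dam_weight`.
#' @param d_col name of the ancestry column in `broodstock` (default
#'   `"true_d"`; use an estimated column for analysis runs).
#' @return data frame with one row per family: ids, brood year, backgrounds,
#'   pair introgression, offspring count and egg metrics.
#' @export
build_family_table <- function(assignments, broodstock, crosses = NULL,
                               d_col = "true_d") {
  ok <- assignments$status == "assigned"
  if (!any(ok)) {
    return(data.frame(dam = character(0), sire = character(0),
                      brood_year = integer(0), n_offspring = integer(0),
                      stringsAsFactors = FALSE))
  }
  a <- assignments[ok, ]
  key <- paste(a$dam, a$sire)
  cnt <- table(key)
  first <- a[!duplicated(key), c("dam", "sire", "assigned_brood_year")]
  first$n_offspring <- as.integer(cnt[paste(first$dam, first$sire)])
  names(first)[3] <- "brood_year"
  bs <- broodstock[match(first$dam, broodstock$id), ]
  sr <- broodstock[match(first$sire, broodstock$id), ]
  first$dam_background <- bs$background
  first$sire_background <- sr$background
  first$pair_introgression <- (bs[[d_col]] + sr[[d_col]]) / 2
  if (!is.null(crosses)) {
    m <- match(paste(first$dam, first$sire), paste(crosses$dam, crosses$sire))
    first$egg_size <- crosses$egg_size[m]
    first$egg_number <- crosses$egg_number[m]
    first$dam_weight <- crosses$dam_weight[m]
  }
  rownames(first) <- NULL
  first
}
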