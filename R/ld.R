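#' EM estimate of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci
#' under the standard two-locus EM: only the double heterozygote is phase
#' ambiguous, and its two resolutions are split in proportion to the
#' current coupling/repulsion haplotype products. Individuals missing
#' either genotype are excluded.
#'
#' @param g1,g2 ALT-dosage vectors (0/1/2, `NA` missing) at the two loci.
#' @param tol Convergence: maximum absolute frequency change below this.
#' @param max_iter Iteration cap.
#' @return Named numeric vector of the four haplotype frequencies
#'   `c(AB, Ab, aB, ab)`, where `A`/`B` denote the ALT alleles at locus 1
#'   and 2, with attributes `n_chrom` (chromosomes used) and `iterations`.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-8, max_iter = 1000) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- length(g1)
  if (n == 0) stop("no individuals with complete genotypes at both loci")
  # genotype-class counts; cells are dosage combinations (d1, d2)
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[g1[i] + 1L, g2[i] + 1L] <- cnt[g1[i] + 1L, g2[i] + 1L] + 1

  # unambiguous haplotype contributions (counts of AB, Ab, aB, ab)
  base <- c(
    AB = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
    Ab = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
    aB = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
    ab = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  )
  n_dh <- cnt[2, 2]  # double heterozygotes: AB/ab or Ab/aB
  f <- rep(0.25, 4)
  names(f) <- names(base)
  it <- 0L
  repeat {
    it <- it + 1L
    coupling <- f["AB"] * f["ab"]
    repulsion <- f["Ab"] * f["aB"]
    w <- if (coupling + repulsion > 0) coupling / (coupling + repulsion) else 0.5
    expected <- base + n_dh * c(w, 1 - w, 1 - w, w)
    f_new <- expected / (2 * n)
    if (max(abs(f_new - f)) < tol || it >= max_iter) { f <- f_new; break }
    f <- f_new
  }
  attr(f, "n_chrom") <- 2L * n
  attr(f, "iterations") <- it
  f
}

#' Linkage-disequilibrium statistics from haplotype frequencies
#'
#' Computes `D = f(AB) - pA*pB`; `D' = |D| / Dmax` with
#' `Dmax = min(pA*pb, pa*pB)` when `D > 0` and `min(pA*pB, pa*pb)`
#' otherwise; `r2 = D^2 / (pA*pa*pB*pb)`; and a chi-square significance
#' test `chi2 = n_chrom * r2` (df = 1, upper tail).
#'
#' @param hap_freqs Frequencies `c(AB, Ab, aB, ab)` summing to 1.
#' @param n_chrom Number of chromosomes behind the estimate.
#' @return List of class `ld_result`: `hap_freqs`, `d`, `d_prime`, `r2`,
#'   `chi2`, `p`, `n_chrom`. A monomorphic locus (allele frequency 0 or 1)
#'   yields `NA` statistics with a warning.
#' @export
ld_stats <- function(hap_freqs, n_chrom) {
  stopifnot(length(hap_freqs) == 4, all(hap_freqs >= 0))
  if (abs(sum(hap_freqs) - 1) > 1e-6)
    stop("haplotype frequencies must sum to 1")
  f <- hap_freqs
  pA <- f[1] + f[2]; pB <- f[1] + f[3]
  pa <- 1 - pA; pb <- 1 - pB
  if (min(pA, pa, pB, pb) <= 0) {
    warning("monomorphic locus: LD undefined")
    return(structure(list(hap_freqs = f, d = NA_real_, d_prime = NA_real_,
                          r2 = NA_real_, chi2 = NA_real_, p = NA_real_,
                          n_chrom = n_chrom), class = "ld_result"))
  }
  d <- unname(f[1] - pA * pB)
  dmax <- if (d > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  d_prime <- if (d == 0) 0 else abs(d) / dmax
  r2 <- unname(d^2 / (pA * pa * pB * pb))
  chi2 <- n_chrom * r2
  structure(list(hap_freqs = f, d = d, d_prime = unname(d_prime), r2 = r2,
                 chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 n_chrom = n_chrom),
            class = "ld_result")
}

#' Pairwise LD between two variants of a genotype matrix
#'
#' Convenience wrapper: EM haplotype frequencies followed by [ld_stats()].
#' By default LD is a population property and is estimated in controls
#' only when phenotypes are supplied.
#'
#' @param genotypes Samples-by-variants dosage matrix (see [genotype-matrix]).
#' @param var_a,var_b Variant ids (column names).
#' @param phenotypes Optional phenotype data frame; when given, only
#'   controls enter the estimate (set `controls_only = FALSE` to override).
#' @param controls_only Restrict to controls when phenotypes are supplied.
#' @return An `ld_result` with `variant_a`/`variant_b` fields added.
#' @export
ld_pair <- function(genotypes, var_a, var_b, phenotypes = NULL,
                    controls_only = TRUE) {
  stopifnot(var_a %in% colnames(genotypes), var_b %in% colnames(genotypes))
  if (!is.null(phenotypes) && controls_only) {
    masks <- split_phenotypes(genotypes, phenotypes)
    genotypes <- genotypes[masks$control, , drop = FALSE]
  }
  f <- em_haplotype_freqs(genotypes[, var_a], genotypes[, var_b])
  res <- ld_stats(as.numeric(f) / sum(f), attr(f, "n_chrom"))
  res$variant_a <- var_a
  res$variant_b <- var_b
  res
}

#' LD table for a set of variant pairs
#'
#' @param genotypes Samples-by-variants dosage matrix.
#' @param pairs Data frame with columns `variant_a`, `variant_b`.
#' @param ... Passed to [ld_pair()].
#' @return Data frame with one row per pair: ids, `d`, `d_prime`, `r2`,
#'   `chi2`, `p`, `n_chrom`.
#' @export
ld_table <- function(genotypes, pairs, ...) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- ld_pair(genotypes, pairs$variant_a[i], pairs$variant_b[i], ...)
    data.frame(variant_a = r$variant_a, variant_b = r$variant_b,
               d = r$d, d_prime = r$d_prime, r2 = r$r2, chi2 = r$chi2,
               p = r$p, n_chrom = r$n_chrom, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
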