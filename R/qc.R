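#' Quality-control thresholds
#'
#' Defaults: variants need a call rate of at least 0.99 (at most 1% failed
#' genotyping), samples at least 0.95, minor allele frequency at least 0.03,
#' Hardy-Weinberg equilibrium p not below 0.05, and only autosomal variants
#' are kept.
#'
#' @param min_sample_call_rate,min_variant_call_rate Call-rate floors.
#' @param min_maf Minor-allele-frequency floor.
#' @param hwe_alpha Variants with HWE p below this are removed; 0 disables
#'   the filter.
#' @param autosomes_only Drop non-autosomal variants first?
#' @param hwe_in_controls Test HWE in controls only (requires phenotypes)?
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sample_call_rate = 0.95,
                          min_variant_call_rate = 0.99,
                          min_maf = 0.03, hwe_alpha = 0.05,
                          autosomes_only = TRUE, hwe_in_controls = TRUE) {
  vals <- c(min_sample_call_rate, min_variant_call_rate, min_maf, hwe_alpha)
  if (any(vals < 0 | vals > 1))
    stop("all QC thresholds must lie in [0, 1]")
  structure(list(min_sample_call_rate = min_sample_call_rate,
                 min_variant_call_rate = min_variant_call_rate,
                 min_maf = min_maf, hwe_alpha = hwe_alpha,
                 autosomes_only = autosomes_only,
                 hwe_in_controls = hwe_in_controls),
            class = "qc_thresholds")
}

#' Per-sample and per-variant call rates
#'
#' @param genotypes Samples-by-variants dosage matrix (see [genotype-matrix]).
#' @return List with numeric vectors `sample` and `variant`, each the
#'   fraction of non-missing calls.
#' @export
call_rates <- function(genotypes) {
  if (!length(genotypes)) stop("empty genotype matrix")
  ok <- !is.na(genotypes)
  list(sample = rowMeans(ok), variant = colMeans(ok))
}

#' Minor allele frequency of one variant
#'
#' `min(p, 1 - p)` where `p` is the ALT-allele count fraction over
#' non-missing diploid calls.
#'
#' @param calls Integer dosage vector (0/1/2, `NA` missing).
#' @return Frequency in \[0, 0.5\].
#' @export
minor_allele_frequency <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) stop("all calls missing")
  p <- sum(calls) / (2 * length(calls))
  min(p, 1 - p)
}

# Column-wise ALT allele frequency (not folded to minor).
alt_freq <- function(genotypes) {
  colSums(genotypes, na.rm = TRUE) / (2 * colSums(!is.na(genotypes)))
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Pearson chi-square (df = 1) of observed genotype counts against the
#' expectation `p^2 : 2pq : q^2` at the estimated allele frequency. A
#' monomorphic variant returns `chi2 = 0`, `p = 1` by convention.
#'
#' @param n_aa,n_ab,n_bb Counts of the three genotype classes
#'   (hom-reference, heterozygote, hom-alternate). Vectorized.
#' @return List with numeric vectors `chi2` and `p`.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (any(n <= 0)) stop("total genotype count must be positive")
  p <- (2 * n_bb + n_ab) / (2 * n)
  e_aa <- n * (1 - p)^2
  e_ab <- n * 2 * p * (1 - p)
  e_bb <- n * p^2
  mono <- p == 0 | p == 1
  chi2 <- ifelse(mono, 0,
                 (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab +
                   (n_bb - e_bb)^2 / e_bb)
  list(chi2 = chi2, p = ifelse(mono, 1, stats::pchisq(chi2, df = 1,
                                                      lower.tail = FALSE)))
}

# HWE p-values per variant column of a genotype matrix.
hwe_p_by_variant <- function(genotypes) {
  n_aa <- colSums(genotypes == 0L, na.rm = TRUE)
  n_ab <- colSums(genotypes == 1L, na.rm = TRUE)
  n_bb <- colSums(genotypes == 2L, na.rm = TRUE)
  tot <- n_aa + n_ab + n_bb
  p <- rep(1, ncol(genotypes))
  idx <- tot > 0
  if (any(idx))
    p[idx] <- hwe_test(n_aa[idx], n_ab[idx], n_bb[idx])$p
  p
}

#' Build a staged QC removal ledger
#'
#' Records how many variants each sequential filter removed and verifies
#' the conservation identity: input = removed (per stage) + kept.
#'
#' @param n_variants_in Number of variants entering QC.
#' @param n_removed_nonautosomal,n_removed_call_rate,n_removed_maf,n_removed_hwe
#'   Variants attributed to each filter (first failing filter wins).
#' @param n_samples_removed Samples removed for low call rate.
#' @return A one-row data frame of class `qc_report` including
#'   `n_variants_kept`.
#' @export
qc_report <- function(n_variants_in, n_removed_nonautosomal = 0,
                      n_removed_call_rate = 0, n_removed_maf = 0,
                      n_removed_hwe = 0, n_samples_removed = 0) {
  kept <- n_variants_in - n_removed_nonautosomal - n_removed_call_rate -
    n_removed_maf - n_removed_hwe
  if (kept < 0) stop("removal counts exceed the number of input variants")
  structure(data.frame(
    n_variants_in = n_variants_in,
    n_removed_nonautosomal = n_removed_nonautosomal,
    n_removed_call_rate = n_removed_call_rate,
    n_samples_removed = n_samples_removed,
    n_removed_maf = n_removed_maf,
    n_removed_hwe = n_removed_hwe,
    n_variants_kept = kept
  ), class = c("qc_report", "data.frame"))
}

#' Apply sequential genotype quality control
#'
#' Filters run in a fixed order, each variant being attributed to the first
#' filter it fails: non-autosomal removal, variant call rate, sample call
#' rate (samples are dropped; earlier variant-stage rates are not
#' recomputed), minor allele frequency, and Hardy-Weinberg equilibrium.
#' MAF and HWE are computed on the samples that survive the sample filter;
#' HWE uses controls only by default.
#'
#' @param genotypes Samples-by-variants dosage matrix (see [genotype-matrix]).
#' @param variants Variant data frame aligned with the matrix columns.
#' @param thresholds A [qc_thresholds()].
#' @param phenotypes Optional phenotype data frame (`sample_id`, `status`);
#'   required when `hwe_in_controls` is `TRUE`.
#' @return List with `genotypes` and `variants` (filtered), `report`
#'   (a [qc_report()]), and `samples_removed` (character vector of ids).
#' @export
apply_qc <- function(genotypes, variants, thresholds = qc_thresholds(),
                     phenotypes = NULL) {
  stopifnot(inherits(thresholds, "qc_thresholds"),
            ncol(genotypes) == nrow(variants))
  n_in <- ncol(genotypes)

  keep_auto <- if (thresholds$autosomes_only) is_autosome(variants$chrom)
               else rep(TRUE, n_in)
  n_nonauto <- sum(!keep_auto)
  geno <- genotypes[, keep_auto, drop = FALSE]
  vars <- variants[keep_auto, , drop = FALSE]

  vr <- colMeans(!is.na(geno))
  fail_cr <- vr < thresholds$min_variant_call_rate
  n_cr <- sum(fail_cr)
  geno <- geno[, !fail_cr, drop = FALSE]
  vars <- vars[!fail_cr, , drop = FALSE]

  sr <- if (ncol(geno) == 0) rep_len(1, nrow(geno))
        else rowMeans(!is.na(geno))
  drop_samples <- sr < thresholds$min_sample_call_rate
  samples_removed <- rownames(geno)[drop_samples]
  geno <- geno[!drop_samples, , drop = FALSE]

  mafs <- apply(geno, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(0)
    p <- sum(x) / (2 * length(x))
    min(p, 1 - p)
  })
  fail_maf <- mafs < thresholds$min_maf
  n_maf <- sum(fail_maf)
  geno <- geno[, !fail_maf, drop = FALSE]
  vars <- vars[!fail_maf, , drop = FALSE]

  if (thresholds$hwe_alpha > 0) {
    hwe_geno <- geno
    if (thresholds$hwe_in_controls) {
      if (is.null(phenotypes))
        stop("phenotypes required to test HWE in controls only")
      masks <- split_phenotypes(geno, phenotypes)
      hwe_geno <- geno[masks$control, , drop = FALSE]
    }
    fail_hwe <- hwe_p_by_variant(hwe_geno) < thresholds$hwe_alpha
  } else {
    fail_hwe <- rep(FALSE, ncol(geno))
  }
  n_hwe <- sum(fail_hwe)
  geno <- geno[, !fail_hwe, drop = FALSE]
  vars <- vars[!fail_hwe, , drop = FALSE]

  list(genotypes = geno, variants = vars,
       report = qc_report(n_variants_in = n_in,
                          n_removed_nonautosomal = n_nonauto,
                          n_removed_call_rate = n_cr,
                          n_removed_maf = n_maf,
                          n_removed_hwe = n_hwe,
                          n_samples_removed = length(samples_removed)),
       samples_removed = samples_removed)
}
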