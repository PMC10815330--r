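#' Allele-count 2x2 table for a single variant
#'
#' Builds the case/control table of effect-allele versus other-allele counts
#' under the allelic (multiplicative) model: each non-missing diploid call
#' contributes two alleles to its group.
#'
#' @param case_calls,control_calls Integer ALT-dosage vectors (0/1/2, `NA`
#'   missing).
#' @param effect `"alt"` (count the ALT allele as the effect allele) or
#'   `"ref"`.
#' @return An object of class `allele_table`: list with counts `a` (case
#'   effect), `b` (case other), `c` (control effect), `d` (control other).
#' @export
allele_table <- function(case_calls, control_calls, effect = c("alt", "ref")) {
  effect <- match.arg(effect)
  case_calls <- case_calls[!is.na(case_calls)]
  control_calls <- control_calls[!is.na(control_calls)]
  if (!length(case_calls) || !length(control_calls))
    stop("no non-missing calls in one of the groups")
  a <- sum(case_calls); b <- 2 * length(case_calls) - a
  c_ <- sum(control_calls); d <- 2 * length(control_calls) - c_
  if (effect == "ref") { tmp <- a; a <- b; b <- tmp; tmp <- c_; c_ <- d; d <- tmp }
  new_allele_table(a, b, c_, d)
}

#' Construct an allele table from raw counts
#'
#' @param a,b Case effect-allele and other-allele counts.
#' @param c,d Control effect-allele and other-allele counts.
#' @return An `allele_table`.
#' @export
new_allele_table <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("allele counts must be non-negative")
  # doubles: products of four margins overflow 32-bit integers
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d)), class = "allele_table")
}

#' Odds ratio of a 2x2 allele table
#'
#' `(a * d) / (b * c)`, no continuity correction. When `b * c = 0` the odds
#' ratio is undefined and `NA` is returned with a warning.
#'
#' @param t An `allele_table`.
#' @return Numeric odds ratio (possibly 0 when `a * d = 0`).
#' @export
odds_ratio <- function(t) {
  stopifnot(inherits(t, "allele_table"))
  if (t$b * t$c == 0) {
    warning("odds ratio undefined: zero denominator cell")
    return(NA_real_)
  }
  (t$a * t$d) / (t$b * t$c)
}

#' Woolf confidence interval for an odds ratio
#'
#' Computed on the log scale: `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Requires all four cells positive; otherwise `NA` bounds with a warning.
#'
#' @param t An `allele_table`.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
woolf_ci <- function(t, level = 0.95) {
  stopifnot(inherits(t, "allele_table"), level > 0, level < 1)
  cells <- c(t$a, t$b, t$c, t$d)
  if (any(cells == 0)) {
    warning("Woolf CI undefined: zero cell")
    return(c(NA_real_, NA_real_))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  lor <- log(odds_ratio(t))
  se <- sqrt(sum(1 / cells))
  exp(lor + c(-1, 1) * z * se)
}

#' Pearson chi-square test of a 2x2 allele table
#'
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without continuity
#' correction; p is the upper tail at df = 1. Degenerate margins return
#' `chi2 = 0`, `p = 1`.
#'
#' @param t An `allele_table`.
#' @return List with `chi2` and `p`.
#' @export
chi2_p <- function(t) {
  stopifnot(inherits(t, "allele_table"))
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  if (n == 0 || denom == 0) return(list(chi2 = 0, p = 1))
  chi2 <- n * (a * d - b * c_)^2 / denom
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Familywise error rate.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha, m) {
  if (m < 1) stop("number of tests must be at least 1")
  alpha / m
}

#' Single-SNP allelic association scan
#'
#' For every variant, compares effect-allele counts between cases and
#' controls under the multiplicative model: odds ratio, Woolf 95% CI and
#' Pearson chi-square p (df = 1). The effect allele is the minor allele in
#' the pooled sample (the reference allele on an exact 0.5 tie); the
#' reciprocal odds ratio for the opposite allele is also reported, as
#' association tables conventionally list both directions.
#'
#' @param genotypes Samples-by-variants dosage matrix (see [genotype-matrix]).
#' @param phenotypes Phenotype data frame (`sample_id`, `status`).
#' @param variants Variant data frame aligned with the matrix columns.
#' @return Data frame sorted by (chrom, pos), one row per variant:
#'   `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `maf_case`, `maf_control`, counts `a`,`b`,`c`,`d`, `or`, `or_other`,
#'   `ci_low`, `ci_high`, `chi2`, `p`.
#' @export
run_gwas <- function(genotypes, phenotypes, variants) {
  stopifnot(ncol(genotypes) == nrow(variants))
  masks <- split_phenotypes(genotypes, phenotypes)
  case_g <- genotypes[masks$case, , drop = FALSE]
  ctl_g <- genotypes[masks$control, , drop = FALSE]

  n_case_ok <- colSums(!is.na(case_g))
  n_ctl_ok <- colSums(!is.na(ctl_g))
  alt_case <- colSums(case_g, na.rm = TRUE)
  alt_ctl <- colSums(ctl_g, na.rm = TRUE)
  pooled_alt <- (alt_case + alt_ctl) / (2 * (n_case_ok + n_ctl_ok))
  alt_is_effect <- pooled_alt < 0.5  # tie -> reference allele is the effect

  a <- ifelse(alt_is_effect, alt_case, 2 * n_case_ok - alt_case)
  b <- 2 * n_case_ok - a
  c_ <- ifelse(alt_is_effect, alt_ctl, 2 * n_ctl_ok - alt_ctl)
  d <- 2 * n_ctl_ok - c_

  or <- ifelse(b * c_ > 0, (a * d) / (b * c_), NA_real_)
  cells_ok <- a > 0 & b > 0 & c_ > 0 & d > 0
  z <- stats::qnorm(0.975)
  se <- ifelse(cells_ok, sqrt(1 / a + 1 / b + 1 / c_ + 1 / d), NA_real_)
  ci_low <- ifelse(cells_ok, exp(log(or) - z * se), NA_real_)
  ci_high <- ifelse(cells_ok, exp(log(or) + z * se), NA_real_)
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  p <- ifelse(denom > 0, stats::pchisq(chi2, 1, lower.tail = FALSE), 1)

  res <- data.frame(
    variant_id = variants$variant_id,
    chrom = variants$chrom,
    pos = variants$pos,
    effect_allele = ifelse(alt_is_effect, variants$alt, variants$ref),
    other_allele = ifelse(alt_is_effect, variants$ref, variants$alt),
    maf_case = a / (2 * n_case_ok),
    maf_control = c_ / (2 * n_ctl_ok),
    a = a, b = b, c = c_, d = d,
    or = or, or_other = 1 / or,
    ci_low = ci_low, ci_high = ci_high,
    chi2 = chi2, p = p,
    stringsAsFactors = FALSE
  )
  chrom_key <- suppressWarnings(as.integer(sub("^chr", "", res$chrom)))
  chrom_key[is.na(chrom_key)] <- 1000L  # X/Y/MT after the autosomes
  res <- res[order(chrom_key, res$pos), ]
  rownames(res) <- NULL
  res
}

#' Export Manhattan-plot data and figure
#'
#' Writes a TSV of `(chrom, pos, neglog10_p)` and, optionally, a Manhattan
#' plot with horizontal reference lines at the genome-wide threshold
#' (5e-8) and a study-internal Bonferroni threshold.
#'
#' @param results A [run_gwas()] table.
#' @param out_tsv Output TSV path.
#' @param out_plot Optional PNG path; `NULL` skips the figure.
#' @param gwas_threshold,bonferroni_threshold Reference-line p-values; the
#'   Bonferroni default is `0.05 / nrow(results)`.
#' @return The exported data frame, invisibly.
#' @export
manhattan_export <- function(results, out_tsv, out_plot = NULL,
                             gwas_threshold = 5e-8,
                             bonferroni_threshold = bonferroni(0.05, nrow(results))) {
  dat <- data.frame(chrom = results$chrom, pos = results$pos,
                    neglog10_p = -log10(results$p),
                    stringsAsFactors = FALSE)
  utils::write.table(dat, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out_plot)) {
    chrom_key <- suppressWarnings(as.integer(sub("^chr", "", dat$chrom)))
    chrom_key[is.na(chrom_key)] <- 1000L
    dat$chrom <- factor(dat$chrom, levels = unique(dat$chrom[order(chrom_key)]))
    gg <- ggplot2::ggplot(dat, ggplot2::aes(x = pos, y = neglog10_p,
                                            colour = chrom)) +
      ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
      ggplot2::facet_grid(cols = ggplot2::vars(chrom), scales = "free_x",
                          space = "free_x", switch = "x") +
      ggplot2::geom_hline(yintercept = -log10(gwas_threshold),
                          linetype = "solid") +
      ggplot2::geom_hline(yintercept = -log10(bonferroni_threshold),
                          linetype = "dashed") +
      ggplot2::labs(x = "chromosome", y = expression(-log[10](p))) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                     panel.spacing = ggplot2::unit(0.1, "lines"))
    ggplot2::ggsave(out_plot, gg, width = 9, height = 3.5, dpi = 150)
  }
  invisible(dat)
}
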