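#' Polarize a SNP pair by stage-1 risk direction
#'
#' At each locus the "negative" allele is the one whose stage-1 allelic
#' odds ratio exceeds 1 (the risk allele); the opposite allele is
#' "positive" (protective). A variant whose both-direction odds ratios
#' equal exactly 1 cannot be polarized and raises an error.
#'
#' @param pair One row of a [build_snp_pairs()] table (or any list with
#'   `variant_a`, `variant_b`).
#' @param results A [run_gwas()] table containing both variants.
#' @return List of class `polarized_pair`: the pair ids plus
#'   `negative_allele_a/b`, `positive_allele_a/b` and logical
#'   `negative_is_alt_a/b` used for dosage orientation.
#' @export
polarize_pair <- function(pair, results) {
  pick <- function(vid) {
    row <- results[results$variant_id == vid, ]
    if (nrow(row) != 1) stop("variant not in stage-1 results: ", vid)
    if (is.na(row$or) || row$or == 1)
      stop("variant cannot be polarized (odds ratio exactly 1): ", vid)
    if (row$or > 1)
      list(neg = row$effect_allele, pos = row$other_allele)
    else
      list(neg = row$other_allele, pos = row$effect_allele)
  }
  pa <- pick(pair$variant_a)
  pb <- pick(pair$variant_b)
  structure(list(
    variant_a = pair$variant_a, variant_b = pair$variant_b,
    gene_a = pair$gene_a, gene_b = pair$gene_b,
    negative_allele_a = pa$neg, positive_allele_a = pa$pos,
    negative_allele_b = pb$neg, positive_allele_b = pb$pos
  ), class = "polarized_pair")
}

# Negative-allele dosage vectors (0/1/2, NA missing) for both loci of a
# polarized pair, oriented via the variant table's ALT allele.
negative_dosages <- function(p, genotypes, variants) {
  orient <- function(vid, neg_allele) {
    alt <- variants$alt[match(vid, variants$variant_id)]
    g <- genotypes[, vid]
    if (identical(neg_allele, alt)) g else 2L - g
  }
  list(a = orient(p$variant_a, p$negative_allele_a),
       b = orient(p$variant_b, p$negative_allele_b))
}

#' Pooled-allele 2x2 table for a polarized SNP pair
#'
#' Each individual contributes up to four alleles (two per locus) to its
#' group's negative/positive counts. A locus with a missing call
#' contributes nothing for that locus only; the other locus still counts,
#' so group totals need not be multiples of four under missingness.
#'
#' @param p A [polarize_pair()] result.
#' @param genotypes Samples-by-variants dosage matrix (see [genotype-matrix]).
#' @param variants Variant data frame aligned with the matrix columns.
#' @param phenotypes Phenotype data frame.
#' @return An `allele_table` with `a` = case negative-allele count,
#'   `b` = case positive, `c` = control negative, `d` = control positive.
#' @export
pooled_allele_table <- function(p, genotypes, variants, phenotypes) {
  stopifnot(inherits(p, "polarized_pair"))
  masks <- split_phenotypes(genotypes, phenotypes)
  dos <- negative_dosages(p, genotypes, variants)
  if (all(is.na(dos$a)) && all(is.na(dos$b)))
    stop("pair has no non-missing genotype data")
  count_group <- function(mask) {
    neg <- sum(dos$a[mask], na.rm = TRUE) + sum(dos$b[mask], na.rm = TRUE)
    tot <- 2 * sum(!is.na(dos$a[mask])) + 2 * sum(!is.na(dos$b[mask]))
    c(neg = neg, pos = tot - neg)
  }
  cs <- count_group(masks$case)
  ct <- count_group(masks$control)
  new_allele_table(unname(cs["neg"]), unname(cs["pos"]),
                   unname(ct["neg"]), unname(ct["pos"]))
}

#' Multiplicative (pooled-allele) test for a SNP pair
#'
#' Odds ratio, Woolf 95% CI and Pearson chi-square p of the pooled
#' negative-versus-positive allele table, sharing the single-SNP
#' machinery ([odds_ratio()], [woolf_ci()], [chi2_p()]).
#'
#' @param t An `allele_table` from [pooled_allele_table()].
#' @return List `or`, `ci_low`, `ci_high`, `chi2`, `p`.
#' @export
multiplicative_test <- function(t) {
  or <- odds_ratio(t)
  ci <- suppressWarnings(woolf_ci(t))
  cp <- chi2_p(t)
  list(or = or, ci_low = ci[1], ci_high = ci[2], chi2 = cp$chi2, p = cp$p)
}

#' Classify a two-locus genotype into haplotype groups I/II/III
#'
#' The nine two-locus genotype combinations are partitioned by the total
#' negative-allele count `k = dosage_a + dosage_b`: `k` in 3-4 is Group I
#' (negative alleles prevail), `k = 2` Group II (balanced), `k` in 0-1
#' Group III (positive alleles prevail) — three combinations per group.
#' Vectorized; symmetric in its two arguments.
#'
#' @param dosage_a,dosage_b Negative-allele dosages (0/1/2).
#' @return Character vector in `c("I", "II", "III")` (`NA` propagates).
#' @export
classify_group <- function(dosage_a, dosage_b) {
  k <- dosage_a + dosage_b
  ifelse(k >= 3, "I", ifelse(k == 2, "II", "III"))
}

#' Haplotype-group counts for a polarized SNP pair
#'
#' Counts cases and controls in Groups I/II/III. Only individuals with
#' complete genotypes at both loci are classified; group membership is
#' undefined otherwise.
#'
#' @inheritParams pooled_allele_table
#' @return List of class `group_counts`: `case_I`, `case_II`, `case_III`,
#'   `control_I`, `control_II`, `control_III`.
#' @export
group_counts <- function(p, genotypes, variants, phenotypes) {
  stopifnot(inherits(p, "polarized_pair"))
  masks <- split_phenotypes(genotypes, phenotypes)
  dos <- negative_dosages(p, genotypes, variants)
  complete <- !is.na(dos$a) & !is.na(dos$b)
  grp <- classify_group(dos$a, dos$b)
  tally <- function(mask) {
    m <- mask & complete
    c(I = sum(grp[m] == "I"), II = sum(grp[m] == "II"),
      III = sum(grp[m] == "III"))
  }
  cs <- tally(masks$case)
  ct <- tally(masks$control)
  structure(list(case_I = unname(cs["I"]), case_II = unname(cs["II"]),
                 case_III = unname(cs["III"]),
                 control_I = unname(ct["I"]), control_II = unname(ct["II"]),
                 control_III = unname(ct["III"])),
            class = "group_counts")
}

#' Additive-model test on haplotype-group counts
#'
#' Contrasts individuals enriched for negative alleles against a baseline:
#' by default Group I versus Group III as a 2x2 table of individuals, with
#' odds ratio, Woolf CI and chi-square p from the shared 2x2 machinery.
#' The contrast is configurable because the strata baseline is a modelling
#' choice: `"I_vs_III"`, `"I_vs_rest"` (I against II+III) or
#' `"II_vs_III"`.
#'
#' @param g A [group_counts()] result.
#' @param contrast Which groups to compare.
#' @return List `or`, `ci_low`, `ci_high`, `chi2`, `p`, `contrast`. An
#'   empty contrast cell yields `NA` effect estimates with a warning.
#' @export
additive_test <- function(g, contrast = c("I_vs_III", "I_vs_rest", "II_vs_III")) {
  stopifnot(inherits(g, "group_counts"))
  contrast <- match.arg(contrast)
  cells <- switch(contrast,
    I_vs_III = c(g$case_I, g$case_III, g$control_I, g$control_III),
    I_vs_rest = c(g$case_I, g$case_II + g$case_III,
                  g$control_I, g$control_II + g$control_III),
    II_vs_III = c(g$case_II, g$case_III, g$control_II, g$control_III))
  t <- new_allele_table(cells[1], cells[2], cells[3], cells[4])
  res <- suppressWarnings(multiplicative_test(t))
  if (any(cells == 0)) warning("empty contrast cell: additive OR/CI undefined")
  c(res, list(contrast = contrast))
}

#' Scan SNP pairs with the multiplicative and additive models
#'
#' For each pair: polarize by stage-1 risk direction, build the pooled
#' negative/positive allele table and test it (multiplicative model), and
#' tabulate haplotype Groups I/II/III and test the configured contrast
#' (additive model). The stage-2 Bonferroni threshold is `alpha` divided
#' by the number of pairs actually tested in this scan.
#'
#' @param pairs A [build_snp_pairs()] table.
#' @param genotypes,variants,phenotypes As in [pooled_allele_table()].
#' @param results Stage-1 [run_gwas()] table (for polarity).
#' @param alpha Familywise level for the stage-2 Bonferroni correction.
#' @param contrast Additive-model contrast, see [additive_test()].
#' @return Data frame sorted by multiplicative p: pair identity, negative/
#'   positive alleles, pooled counts (`case_neg`, `case_pos`,
#'   `control_neg`, `control_pos`), `mult_or`, `mult_ci_low`,
#'   `mult_ci_high`, `mult_p`, the six group counts, `add_or`,
#'   `add_ci_low`, `add_ci_high`, `add_p`, and `passes_bonferroni`. The
#'   threshold used is attached as attribute `bonferroni_threshold`.
#' @export
pair_scan <- function(pairs, genotypes, variants, phenotypes, results,
                      alpha = 0.05, contrast = "I_vs_III") {
  if (nrow(pairs) < 1) stop("no pairs to scan")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    out <- try({
      p <- polarize_pair(pr, results)
      t <- pooled_allele_table(p, genotypes, variants, phenotypes)
      mt <- suppressWarnings(multiplicative_test(t))
      g <- group_counts(p, genotypes, variants, phenotypes)
      at <- suppressWarnings(additive_test(g, contrast))
      data.frame(
        variant_a = p$variant_a, variant_b = p$variant_b,
        gene_a = if (is.null(p$gene_a)) NA_character_ else p$gene_a,
        gene_b = if (is.null(p$gene_b)) NA_character_ else p$gene_b,
        negative_allele_a = p$negative_allele_a,
        positive_allele_a = p$positive_allele_a,
        negative_allele_b = p$negative_allele_b,
        positive_allele_b = p$positive_allele_b,
        case_neg = t$a, case_pos = t$b,
        control_neg = t$c, control_pos = t$d,
        mult_or = mt$or, mult_ci_low = mt$ci_low,
        mult_ci_high = mt$ci_high, mult_p = mt$p,
        case_I = g$case_I, case_II = g$case_II, case_III = g$case_III,
        control_I = g$control_I, control_II = g$control_II,
        control_III = g$control_III,
        add_or = at$or, add_ci_low = at$ci_low, add_ci_high = at$ci_high,
        add_p = at$p,
        stringsAsFactors = FALSE
      )
    }, silent = TRUE)
    if (inherits(out, "try-error")) {
      warning("pair ", pr$variant_a, "/", pr$variant_b, " failed: ",
              attr(out, "condition")$message)
      return(NULL)
    }
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("all pairs failed")
  threshold <- bonferroni(alpha, nrow(res))
  res$passes_bonferroni <- res$mult_p < threshold
  res <- res[order(res$mult_p), ]
  rownames(res) <- NULL
  attr(res, "bonferroni_threshold") <- threshold
  res
}
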