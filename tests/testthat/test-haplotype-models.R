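# Two-variant scaffold with explicit alleles for polarity checks.
pair_scaffold <- function(case_a, case_b, ctl_a, ctl_b) {
  n_case <- length(case_a); n_ctl <- length(ctl_a)
  geno <- cbind(vA = c(case_a, ctl_a), vB = c(case_b, ctl_b))
  rownames(geno) <- sprintf("s%03d", seq_len(n_case + n_ctl))
  variants <- data.frame(variant_id = c("vA", "vB"), chrom = "1",
                         pos = c(1L, 2L), ref = c("A", "T"),
                         alt = c("G", "C"), stringsAsFactors = FALSE)
  phen <- data.frame(sample_id = rownames(geno),
                     status = rep(c("case", "control"), c(n_case, n_ctl)),
                     stringsAsFactors = FALSE)
  list(genotypes = geno, variants = variants, phenotypes = phen)
}

stage1_rows <- function(or_a, or_b) {
  data.frame(variant_id = c("vA", "vB"), chrom = "1", pos = c(1L, 2L),
             effect_allele = c("G", "C"), other_allele = c("A", "T"),
             maf_case = 0.2, maf_control = 0.15, a = 1, b = 1, c = 1, d = 1,
             or = c(or_a, or_b), or_other = 1 / c(or_a, or_b),
             ci_low = NA, ci_high = NA, chi2 = 1, p = 0.01,
             stringsAsFactors = FALSE)
}

test_that("polarity follows the OR > 1 direction and survives label swaps", {
  pair <- list(variant_a = "vA", variant_b = "vB")
  p <- polarize_pair(pair, stage1_rows(2.0, 0.5))
  expect_equal(p$negative_allele_a, "G")
  expect_equal(p$positive_allele_a, "A")
  # vB's ALT (C) has OR 0.5, so the risk allele is the REF (T)
  expect_equal(p$negative_allele_b, "T")
  # swapping the stage-1 effect/other labels leaves polarity unchanged
  swapped <- stage1_rows(2.0, 0.5)
  swapped[2, c("effect_allele", "other_allele")] <- c("T", "C")
  swapped$or[2] <- 2.0; swapped$or_other[2] <- 0.5
  p2 <- polarize_pair(pair, swapped)
  expect_equal(p2$negative_allele_b, p$negative_allele_b)
  expect_error(polarize_pair(pair, stage1_rows(1.0, 2.0)), "polarized")
})

test_that("pooled allele tables count up to four alleles per individual", {
  # one case homozygous for the negative allele at both loci
  fix <- pair_scaffold(case_a = 2L, case_b = 0L, ctl_a = 0L, ctl_b = 2L)
  # vB negative allele is REF (T): case dosage 0 means two negative alleles
  p <- polarize_pair(list(variant_a = "vA", variant_b = "vB"),
                     stage1_rows(2.0, 0.5))
  t <- pooled_allele_table(p, fix$genotypes, fix$variants, fix$phenotypes)
  expect_equal(unlist(t[c("a", "b")]), c(a = 4, b = 0))
  # the control is hom-positive at both loci
  expect_equal(unlist(t[c("c", "d")]), c(c = 0, d = 4))
})

test_that("complete data gives 4x group-size totals; each missing call drops 2", {
  set.seed(61)
  n_case <- 144; n_ctl <- 163
  fix <- pair_scaffold(rbinom(n_case, 2, 0.2), rbinom(n_case, 2, 0.3),
                       rbinom(n_ctl, 2, 0.2), rbinom(n_ctl, 2, 0.3))
  p <- polarize_pair(list(variant_a = "vA", variant_b = "vB"),
                     stage1_rows(2.0, 1.5))
  t <- pooled_allele_table(p, fix$genotypes, fix$variants, fix$phenotypes)
  expect_equal(t$a + t$b, 2 * 144 + 2 * 144)   # 576 case alleles
  expect_equal(t$c + t$d, 4 * 163)
  # knock out three control calls at one locus: total drops by exactly 6
  g2 <- fix$genotypes
  g2[n_case + 1:3, "vB"] <- NA
  t2 <- pooled_allele_table(p, g2, fix$variants, fix$phenotypes)
  expect_equal(t2$c + t2$d, 4 * 163 - 6)
  expect_equal(t2$a + t2$b, 576)
})

test_that("pooled counting matches brute-force enumeration with missingness", {
  set.seed(71)
  for (rep_i in 1:10) {
    n <- 20
    ga <- sample(c(0:2, NA), n, replace = TRUE)
    gb <- sample(c(0:2, NA), n, replace = TRUE)
    is_case <- rep(c(TRUE, FALSE), each = n / 2)
    fix <- pair_scaffold(ga[is_case], gb[is_case],
                         ga[!is_case], gb[!is_case])
    p <- polarize_pair(list(variant_a = "vA", variant_b = "vB"),
                       stage1_rows(2.0, 0.5))
    t <- pooled_allele_table(p, fix$genotypes, fix$variants, fix$phenotypes)
    # negative dosage: ALT for vA, 2 - dosage for vB (negative = REF)
    brute <- brute_pooled_table(ga, 2L - gb, is_case)
    expect_equal(unlist(t[c("a", "b", "c", "d")]), brute)
  }
})

test_that("multiplicative pair test shares the 2x2 machinery", {
  t <- new_allele_table(103, 473, 60, 592)
  mt <- multiplicative_test(t)
  expect_equal(round(mt$or, 2), 2.15)
  expect_equal(signif(mt$p, 2), 7.7e-6)
  expect_equal(mt$or, odds_ratio(t))
  expect_equal(c(mt$ci_low, mt$ci_high), woolf_ci(t))
  expect_equal(mt$p, chi2_p(t)$p)
})

test_that("the nine genotype combinations split 3/3/3 into groups", {
  combos <- expand.grid(da = 0:2, db = 0:2)
  grp <- classify_group(combos$da, combos$db)
  expect_equal(as.vector(table(factor(grp, c("I", "II", "III")))),
               c(3, 3, 3))
  expect_equal(classify_group(2, 2), "I")
  expect_equal(classify_group(1, 1), "II")
  expect_equal(classify_group(0, 0), "III")
  # symmetry
  expect_equal(classify_group(combos$da, combos$db),
               classify_group(combos$db, combos$da))
})

test_that("group counts cover exactly the complete-data individuals", {
  fix <- pair_scaffold(case_a = c(2L, 1L, NA), case_b = c(0L, 1L, 0L),
                       ctl_a = c(0L, 0L), ctl_b = c(2L, 1L))
  p <- polarize_pair(list(variant_a = "vA", variant_b = "vB"),
                     stage1_rows(2.0, 0.5))
  g <- group_counts(p, fix$genotypes, fix$variants, fix$phenotypes)
  # case 1: dosages (2, 2-0=2) -> I; case 2: (1, 1) -> II; case 3 dropped
  expect_equal(c(g$case_I, g$case_II, g$case_III), c(1, 1, 0))
  # controls: (0, 2-2=0) -> k=0 -> III; (0, 2-1=1) -> k=1 -> III
  expect_equal(c(g$control_I, g$control_II, g$control_III), c(0, 0, 2))
  expect_equal(g$case_I + g$case_II + g$case_III, 2)
})

test_that("additive contrasts behave on symmetric and degenerate counts", {
  g <- structure(list(case_I = 10, case_II = 7, case_III = 10,
                      control_I = 10, control_II = 9, control_III = 10),
                 class = "group_counts")
  at <- additive_test(g)
  expect_equal(at$or, 1)
  expect_equal(at$p, 1)
  expect_equal(at$contrast, "I_vs_III")
  at2 <- additive_test(g, "I_vs_rest")
  expect_equal(at2$contrast, "I_vs_rest")
  g0 <- structure(list(case_I = 0, case_II = 5, case_III = 10,
                       control_I = 4, control_II = 5, control_III = 10),
                  class = "group_counts")
  expect_warning(at0 <- additive_test(g0), "empty contrast cell")
  expect_true(is.na(at0$ci_low))
})

test_that("pair_scan applies the run-derived Bonferroni divisor and sorts by p", {
  set.seed(83)
  n_case <- 300; n_ctl <- 300
  # locus pair with a real joint effect plus an unrelated null pair
  k_case <- sample(0:2, n_case, replace = TRUE, prob = c(0.3, 0.5, 0.2))
  fix_g <- cbind(
    vA = c(rbinom(n_case, 2, 0.25 + 0.1), rbinom(n_ctl, 2, 0.25)),
    vB = c(rbinom(n_case, 2, 0.35 + 0.1), rbinom(n_ctl, 2, 0.35)),
    vC = rbinom(n_case + n_ctl, 2, 0.3),
    vD = rbinom(n_case + n_ctl, 2, 0.3))
  rownames(fix_g) <- sprintf("s%03d", seq_len(n_case + n_ctl))
  variants <- data.frame(variant_id = c("vA", "vB", "vC", "vD"),
                         chrom = "1", pos = 1:4,
                         ref = c("A", "T", "A", "T"),
                         alt = c("G", "C", "G", "C"),
                         stringsAsFactors = FALSE)
  phen <- data.frame(sample_id = rownames(fix_g),
                     status = rep(c("case", "control"), c(n_case, n_ctl)),
                     stringsAsFactors = FALSE)
  res <- run_gwas(fix_g, phen, variants)
  pairs <- data.frame(variant_a = c("vA", "vC"), variant_b = c("vB", "vD"),
                      gene_a = c("G1", "G3"), gene_b = c("G2", "G4"),
                      edge_score = 0.9, stringsAsFactors = FALSE)
  scan <- pair_scan(pairs, fix_g, variants, phen, res)
  expect_equal(attr(scan, "bonferroni_threshold"), 0.05 / 2)
  expect_equal(scan$mult_p, sort(scan$mult_p))
  expect_true(all(scan$passes_bonferroni ==
                    (scan$mult_p < attr(scan, "bonferroni_threshold"))))
  # single pair: threshold is just alpha
  scan1 <- pair_scan(pairs[1, ], fix_g, variants, phen, res)
  expect_equal(attr(scan1, "bonferroni_threshold"), 0.05)
  # group totals match the complete-genotype counts
  expect_equal(scan$case_I + scan$case_II + scan$case_III,
               rep(n_case, 2))
})
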