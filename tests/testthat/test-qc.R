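test_that("call rates count non-missing calls per sample and per variant", {
  full <- matrix(1L, 4, 5, dimnames = list(paste0("s", 1:4), paste0("v", 1:5)))
  cr <- call_rates(full)
  expect_true(all(cr$sample == 1) && all(cr$variant == 1))

  one <- matrix(0L, 1, 100)
  one[1, 1:5] <- NA
  expect_equal(unname(call_rates(one)$sample), 0.95)

  set.seed(11)
  m <- matrix(sample(c(0:2, NA), 100, replace = TRUE), 10, 10)
  cr <- call_rates(m)
  # exhaustive count oracle
  for (i in 1:10) {
    expect_equal(cr$sample[i], sum(!is.na(m[i, ])) / 10)
    expect_equal(cr$variant[i], sum(!is.na(m[, i])) / 10)
  }
  expect_error(call_rates(matrix(integer(0), 0, 0)), "empty")
})

test_that("minor allele frequency folds the allele-count fraction", {
  expect_equal(minor_allele_frequency(rep(0L, 20)), 0)
  # 144 diploid cases with ALT dosage summing to 84 of 288 alleles
  calls <- c(rep(2L, 10), rep(1L, 64), rep(0L, 70))
  expect_equal(sum(calls), 84)
  expect_equal(round(minor_allele_frequency(calls), 2), 0.29)
  # counting oracle on a random vector, including the folded side
  set.seed(3)
  for (rep_i in 1:20) {
    x <- sample(c(0:2, NA), 30, replace = TRUE,
                prob = c(0.1, 0.2, 0.6, 0.1))
    ok <- x[!is.na(x)]
    p <- sum(ok) / (2 * length(ok))
    expect_equal(minor_allele_frequency(x), min(p, 1 - p))
  }
  expect_error(minor_allele_frequency(c(NA_integer_, NA_integer_)), "missing")
})

test_that("HWE chi-square matches the direct formula and its conventions", {
  r <- hwe_test(25, 50, 25)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  r <- hwe_test(36, 48, 16)
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)
  # direct formula oracle at p-hat = 0.5
  n <- 100; p <- 0.5
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(30, 40, 30)
  expect_equal(hwe_test(30, 40, 30)$chi2, sum((o - e)^2 / e))
  # monomorphic convention
  r <- hwe_test(50, 0, 0)
  expect_equal(c(r$chi2, r$p), c(0, 1))
  expect_error(hwe_test(0, 0, 0), "positive")
})

test_that("sequential QC attributes each variant to its first failing filter", {
  set.seed(42)
  n <- 80
  n_var <- 500
  geno <- matrix(stats::rbinom(n * n_var, 2L, 0.3), n, n_var,
                 dimnames = list(sprintf("s%03d", 1:n), sprintf("v%03d", 1:n_var)))
  # plant failures: 1-20 heavy missingness, 21-40 rare, 41-60 HWE-violating
  geno[sample(n, 40), 1:20] <- NA
  geno[, 21:40] <- rbinom(n * 20, 2L, 0.005)
  geno[, 41:60] <- sample(c(0L, 2L), n * 20, replace = TRUE)  # no hets
  variants <- data.frame(variant_id = colnames(geno),
                         chrom = rep(c("1", "X"), c(n_var - 10, 10)),
                         pos = seq_len(n_var), ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  phen <- data.frame(sample_id = rownames(geno),
                     status = rep(c("case", "control"), each = n / 2),
                     stringsAsFactors = FALSE)
  thr <- qc_thresholds()
  out <- apply_qc(geno, variants, thr, phen)
  rep_ <- out$report

  # independent per-variant classifier, applied in the same stage order
  auto <- variants$chrom %in% as.character(1:22)
  cr <- colMeans(!is.na(geno[, auto, drop = FALSE]))
  fail_cr <- cr < thr$min_variant_call_rate
  survivors <- which(auto)[!fail_cr]
  sr <- rowMeans(!is.na(geno[, survivors, drop = FALSE]))
  keep_s <- sr >= thr$min_sample_call_rate
  ctl <- keep_s & phen$status == "control"
  mafs <- apply(geno[keep_s, survivors, drop = FALSE], 2, function(x) {
    x <- x[!is.na(x)]; p <- sum(x) / (2 * length(x)); min(p, 1 - p)
  })
  fail_maf <- mafs < thr$min_maf
  hwe_p <- vapply(survivors[!fail_maf], function(j) {
    x <- geno[ctl, j]; x <- x[!is.na(x)]
    hwe_test(sum(x == 0), sum(x == 1), sum(x == 2))$p
  }, numeric(1))
  fail_hwe <- hwe_p < thr$hwe_alpha

  expect_equal(rep_$n_removed_nonautosomal, sum(!auto))
  expect_equal(rep_$n_removed_call_rate, sum(fail_cr))
  expect_equal(rep_$n_samples_removed, sum(!keep_s))
  expect_equal(rep_$n_removed_maf, sum(fail_maf))
  expect_equal(rep_$n_removed_hwe, sum(fail_hwe))
  # conservation
  expect_equal(rep_$n_variants_in,
               rep_$n_removed_nonautosomal + rep_$n_removed_call_rate +
                 rep_$n_removed_maf + rep_$n_removed_hwe +
                 rep_$n_variants_kept)
  expect_equal(ncol(out$genotypes), rep_$n_variants_kept)
})

test_that("QC is an identity under permissive thresholds and is idempotent", {
  fix <- tiny_cohort()
  permissive <- qc_thresholds(min_sample_call_rate = 0,
                              min_variant_call_rate = 0, min_maf = 0,
                              hwe_alpha = 0, autosomes_only = FALSE)
  out <- apply_qc(fix$genotypes, fix$variants, permissive, fix$phenotypes)
  expect_identical(out$genotypes, fix$genotypes)
  expect_equal(out$report$n_variants_kept, 4)
  expect_true(all(out$report[grep("removed", names(out$report))] == 0))

  # idempotence under the defaults
  thr <- qc_thresholds(min_maf = 0.1)
  once <- apply_qc(fix$genotypes, fix$variants, thr, fix$phenotypes)
  twice <- apply_qc(once$genotypes, once$variants, thr, fix$phenotypes)
  expect_identical(twice$genotypes, once$genotypes)
  expect_equal(twice$report$n_variants_kept, once$report$n_variants_kept)
})

test_that("raising the MAF floor never keeps more variants", {
  set.seed(9)
  geno <- matrix(stats::rbinom(50 * 100, 2L, runif(100, 0.01, 0.5)),
                 50, 100, byrow = TRUE,
                 dimnames = list(paste0("s", 1:50), paste0("v", 1:100)))
  variants <- data.frame(variant_id = colnames(geno), chrom = "1",
                         pos = 1:100, ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  phen <- data.frame(sample_id = rownames(geno),
                     status = rep(c("case", "control"), 25),
                     stringsAsFactors = FALSE)
  kept <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(m) {
    apply_qc(geno, variants, qc_thresholds(min_maf = m, hwe_alpha = 0),
             phen)$report$n_variants_kept
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("qc_report enforces the conservation identity", {
  r <- qc_report(100, n_removed_call_rate = 30, n_removed_maf = 20)
  expect_equal(r$n_variants_kept, 50)
  expect_error(qc_report(10, n_removed_call_rate = 20), "exceed")
  expect_error(qc_thresholds(min_maf = 1.5), "0, 1")
})
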