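# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# A tiny hand-built cohort: 6 samples (3 cases, 3 controls), 4 variants.
# Variant 3 has a missing call in sample 2; variant 4 is X-labelled.
tiny_cohort <- function() {
  geno <- matrix(
    c(2L, 1L, 0L, 1L, 0L, 0L,   # v1
      1L, 1L, 1L, 1L, 1L, 1L,   # v2
      0L, NA, 2L, 0L, 1L, 0L,   # v3
      0L, 0L, 1L, 0L, 0L, 1L),  # v4 (X)
    nrow = 6
  )
  rownames(geno) <- paste0("S", 1:6)
  colnames(geno) <- paste0("v", 1:4)
  variants <- data.frame(
    variant_id = paste0("v", 1:4),
    chrom = c("1", "2", "2", "X"),
    pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"),
    alt = c("G", "T", "A", "C"),
    stringsAsFactors = FALSE
  )
  phenotypes <- data.frame(
    sample_id = paste0("S", 1:6),
    status = rep(c("case", "control"), each = 3),
    stringsAsFactors = FALSE
  )
  list(genotypes = geno, variants = variants, phenotypes = phenotypes)
}

# Independent brute-force pooled-allele counter: loops over individuals
# and loci, counting negative/positive alleles one call at a time.
brute_pooled_table <- function(neg_dos_a, neg_dos_b, is_case) {
  counts <- c(a = 0, b = 0, c = 0, d = 0)
  for (i in seq_along(is_case)) {
    for (d_i in c(neg_dos_a[i], neg_dos_b[i])) {
      if (is.na(d_i)) next
      if (is_case[i]) {
        counts["a"] <- counts["a"] + d_i
        counts["b"] <- counts["b"] + (2 - d_i)
      } else {
        counts["c"] <- counts["c"] + d_i
        counts["d"] <- counts["d"] + (2 - d_i)
      }
    }
  }
  counts
}

# Log-likelihood of unphased two-locus genotype counts given haplotype
# frequencies f = c(AB, Ab, aB, ab). cnt is the 3x3 dosage-class table
# (rows: dosage at locus 1 = 0,1,2; columns: locus 2).
hap_loglik <- function(cnt, f) {
  fAB <- f[1]; fAb <- f[2]; faB <- f[3]; fab <- f[4]
  prob <- matrix(0, 3, 3)
  prob[1, 1] <- fab^2
  prob[1, 2] <- 2 * fab * faB
  prob[1, 3] <- faB^2
  prob[2, 1] <- 2 * fab * fAb
  prob[2, 2] <- 2 * fAB * fab + 2 * fAb * faB
  prob[2, 3] <- 2 * fAB * faB
  prob[3, 1] <- fAb^2
  prob[3, 2] <- 2 * fAB * fAb
  prob[3, 3] <- fAB^2
  sum(cnt[cnt > 0] * log(prob[cnt > 0]))
}

# 3x3 dosage-class count table for two dosage vectors (NA pairs dropped).
dosage_class_counts <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  table(factor(g1[keep], levels = 0:2), factor(g2[keep], levels = 0:2))
}
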