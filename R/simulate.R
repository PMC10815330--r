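#' Configuration for the synthetic case-control generator
#'
#' Defaults emulate the study design the pipeline targets: 144 cases and 163
#' controls of genotyped autosomal biallelic SNPs, a minor-allele-frequency
#' floor of 3%, and 1% per-genotype missingness. Controls are drawn under
#' Hardy-Weinberg equilibrium at the per-variant ALT-allele frequencies;
#' cases are drawn from a multiplicative risk model in which each copy of
#' a planted risk allele multiplies the baseline disease probability (see
#' [simulate_cohort()]).
#'
#' @param n_case,n_control Group sizes.
#' @param n_variants Number of autosomal variants.
#' @param maf_range Length-2 vector; per-variant ALT-allele frequencies are
#'   drawn uniformly from this interval. Both ends in (0, 0.5].
#' @param missing_rate Per-genotype probability of a missing call
#'   (completely at random).
#' @param ld_blocks Optional list of `list(size =, r2 =)` blocks. Blocks
#'   occupy consecutive variants starting at variant 1, in list order; each
#'   block shares the ALT frequency of its first variant and within-block
#'   haplotypes are copies of a founder allele with a per-site redraw
#'   probability `1 - sqrt(r2)`, so the expected allelic correlation
#'   squared equals `r2` (exact duplication when `r2 = 1`).
#' @param snp_effects Optional data frame `index`, `or`: per-ALT-allele
#'   odds ratios planted at single variants.
#' @param pair_effects Optional data frame `index_a`, `index_b`, `or`: odds
#'   multiplied by `or` per risk (ALT) allele counted over both loci.
#' @param prevalence Baseline disease probability for an individual
#'   carrying no risk alleles.
#' @param n_x_decoy Number of additional X-labelled null variants appended
#'   after the autosomes (to exercise the autosome filter).
#' @param seed Integer seed; fixed seed gives a byte-identical cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_case = 144, n_control = 163, n_variants = 100,
                       maf_range = c(0.03, 0.5), missing_rate = 0.01,
                       ld_blocks = list(), snp_effects = NULL,
                       pair_effects = NULL, prevalence = 0.05,
                       n_x_decoy = 0, seed = 1) {
  stopifnot(n_case > 0, n_control > 0, n_variants > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            missing_rate >= 0, missing_rate <= 1,
            prevalence > 0, prevalence < 1, n_x_decoy >= 0)
  if (!is.null(snp_effects)) {
    stopifnot(all(c("index", "or") %in% names(snp_effects)),
              all(snp_effects$or > 0),
              all(snp_effects$index >= 1 & snp_effects$index <= n_variants))
  }
  if (!is.null(pair_effects)) {
    stopifnot(all(c("index_a", "index_b", "or") %in% names(pair_effects)),
              all(pair_effects$or > 0),
              all(unlist(pair_effects[c("index_a", "index_b")]) >= 1),
              all(unlist(pair_effects[c("index_a", "index_b")]) <= n_variants),
              all(pair_effects$index_a != pair_effects$index_b))
  }
  for (b in ld_blocks)
    stopifnot(b$size >= 2, b$r2 >= 0, b$r2 <= 1)
  if (sum(vapply(ld_blocks, `[[`, numeric(1), "size")) > n_variants)
    stop("ld_blocks cover more variants than n_variants")
  structure(list(n_case = n_case, n_control = n_control,
                 n_variants = n_variants, maf_range = maf_range,
                 missing_rate = missing_rate, ld_blocks = ld_blocks,
                 snp_effects = snp_effects, pair_effects = pair_effects,
                 prevalence = prevalence, n_x_decoy = n_x_decoy,
                 seed = seed),
            class = "sim_config")
}

# Draw n individuals' genotypes (rows) at all variants under HWE, honouring
# LD blocks: each haplotype carries a founder allele per block that sites
# copy, redrawing from Bernoulli(p) with probability 1 - sqrt(r2).
draw_genotypes <- function(n, maf, block_of, block_r2) {
  v <- length(maf)
  hap <- function() {
    h <- matrix(stats::rbinom(n * v, 1L, rep(maf, each = n)), nrow = n)
    for (blk in unique(block_of[!is.na(block_of)])) {
      sites <- which(block_of == blk)
      p <- maf[sites[1]]
      founder <- stats::rbinom(n, 1L, p)
      keep_p <- sqrt(block_r2[blk])
      for (s in sites) {
        keep <- stats::runif(n) < keep_p
        h[, s] <- ifelse(keep, founder, stats::rbinom(n, 1L, p))
      }
    }
    h
  }
  hap() + hap()
}

#' Simulate a case-control cohort
#'
#' Controls are genotype draws under Hardy-Weinberg equilibrium at the
#' configured allele frequencies. Cases are produced by weighted rejection
#' sampling from the multiplicative risk model: candidate individuals are
#' drawn from the same population and accepted as cases with probability
#' `prevalence * prod(or_i ^ g_i)`, the product running over planted
#' single-SNP effects (dosage `g_i`) and planted pair effects (risk-allele
#' count over both loci), until `n_case` cases accrue. Under this model the
#' case genotypes at an effect locus remain in Hardy-Weinberg proportions
#' at a shifted allele frequency, and the planted odds ratio is exactly the
#' allelic odds ratio of cases against the population the controls are
#' drawn from. The model must keep `prevalence * max risk <= 1`.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `genotypes`,
#'   `phenotypes`, `variants` and `truth` (the planted effects, allele
#'   frequencies and prevalence).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  v <- config$n_variants
  maf <- stats::runif(v, config$maf_range[1], config$maf_range[2])

  block_of <- rep(NA_integer_, v)
  block_r2 <- numeric(0)
  at <- 1L
  for (i in seq_along(config$ld_blocks)) {
    b <- config$ld_blocks[[i]]
    block_of[at:(at + b$size - 1L)] <- i
    block_r2[i] <- b$r2
    at <- at + b$size
  }

  beta <- rep(0, v)
  if (!is.null(config$snp_effects))
    beta[config$snp_effects$index] <-
      beta[config$snp_effects$index] + log(config$snp_effects$or)
  if (!is.null(config$pair_effects)) {
    for (k in seq_len(nrow(config$pair_effects))) {
      pe <- config$pair_effects[k, ]
      beta[pe$index_a] <- beta[pe$index_a] + log(pe$or)
      beta[pe$index_b] <- beta[pe$index_b] + log(pe$or)
    }
  }

  controls <- draw_genotypes(config$n_control, maf, block_of, block_r2)

  # P(case | g) = prevalence * prod OR^dosage must stay a probability
  max_risk <- config$prevalence * exp(2 * sum(pmax(beta, 0)))
  if (max_risk > 1)
    stop("disease model exceeds probability 1 for the highest-risk ",
         "genotype: lower prevalence = ", config$prevalence,
         " or the planted odds ratios")

  cases <- matrix(0L, nrow = 0, ncol = v)
  max_draws <- max(1e6, ceiling(50 * config$n_case / config$prevalence))
  drawn <- 0L
  batch <- max(1000L, ceiling(config$n_case / config$prevalence / 4))
  while (nrow(cases) < config$n_case) {
    if (drawn >= max_draws)
      stop("disease model produced too few cases after ", drawn,
           " draws; check n_case = ", config$n_case,
           " against prevalence = ", config$prevalence)
    g <- draw_genotypes(batch, maf, block_of, block_r2)
    drawn <- drawn + batch
    p_case <- config$prevalence * exp(as.vector(g %*% beta))
    accept <- stats::runif(batch) < p_case
    cases <- rbind(cases, g[accept, , drop = FALSE])
  }
  cases <- cases[seq_len(config$n_case), , drop = FALSE]

  geno <- rbind(cases, controls)
  n <- nrow(geno)
  if (config$missing_rate > 0)
    geno[stats::runif(n * v) < config$missing_rate] <- NA_integer_

  # X-labelled null decoys, drawn under HWE with no effects or missingness
  # handling distinct from the autosomes
  if (config$n_x_decoy > 0) {
    xmaf <- stats::runif(config$n_x_decoy, config$maf_range[1], config$maf_range[2])
    xg <- matrix(stats::rbinom(n * config$n_x_decoy, 2L, rep(xmaf, each = n)),
                 nrow = n)
    if (config$missing_rate > 0)
      xg[stats::runif(length(xg)) < config$missing_rate] <- NA_integer_
    geno <- cbind(geno, xg)
  }

  v_all <- v + config$n_x_decoy
  per_chrom <- ceiling(v / 22)
  chrom <- c(as.character(rep(1:22, each = per_chrom, length.out = v)),
             rep("X", config$n_x_decoy))
  pos <- c(10000L * (((seq_len(v) - 1L) %% per_chrom) + 1L),
           if (config$n_x_decoy > 0) 10000L * seq_len(config$n_x_decoy))
  pair_bases <- matrix(c("A", "G", "C", "T", "T", "C", "G", "A"),
                       ncol = 2, byrow = TRUE)
  base_row <- ((seq_len(v_all) - 1L) %% 4L) + 1L
  variants <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(v_all)),
    chrom = chrom, pos = pos,
    ref = pair_bases[base_row, 1], alt = pair_bases[base_row, 2],
    stringsAsFactors = FALSE
  )
  rownames(geno) <- sprintf("S%04d", seq_len(n))
  colnames(geno) <- variants$variant_id
  phenotypes <- data.frame(
    sample_id = rownames(geno),
    status = rep(c("case", "control"), c(config$n_case, config$n_control)),
    stringsAsFactors = FALSE
  )
  structure(list(
    genotypes = geno, phenotypes = phenotypes, variants = variants,
    truth = list(maf = maf, snp_effects = config$snp_effects,
                 pair_effects = config$pair_effects,
                 prevalence = config$prevalence, config = config)
  ), class = "synthetic_cohort")
}

#' Write a synthetic cohort as analysis-ready fixture files
#'
#' Writes four files into `out_dir`: `genotypes.vcf` (GT calls, `./.` for
#' missing), `phenotypes.tsv`, `annotation.tsv` and `ppi.tsv`. Variants
#' carrying a planted pair effect are annotated as exonic in two distinct
#' genes that the PPI table connects with a high-confidence edge (score 900
#' on the STRING 0-999 scale); remaining variants cycle through exon /
#' intron / intergenic in their own per-variant genes. The PPI table also
#' carries a sub-threshold decoy edge. All outputs are deterministic given
#' the cohort.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_fixtures <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             pheno = file.path(out_dir, "phenotypes.tsv"),
             annot = file.path(out_dir, "annotation.tsv"),
             ppi = file.path(out_dir, "ppi.tsv"))
  write_genotype_vcf(cohort$genotypes, cohort$variants, paths["vcf"])
  utils::write.table(cohort$phenotypes, paths["pheno"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  v_all <- nrow(cohort$variants)
  gene <- sprintf("GENE%04d", seq_len(v_all))
  region <- rep(c("exon", "intron", "intergenic"), length.out = v_all)
  pe <- cohort$truth$pair_effects
  edges <- data.frame(protein1 = character(0), protein2 = character(0),
                      score = integer(0), stringsAsFactors = FALSE)
  if (!is.null(pe)) {
    for (k in seq_len(nrow(pe))) {
      ia <- pe$index_a[k]; ib <- pe$index_b[k]
      gene[c(ia, ib)] <- sprintf("PAIR%02d%s", k, c("A", "B"))
      region[c(ia, ib)] <- "exon"
      edges <- rbind(edges, data.frame(protein1 = gene[ia], protein2 = gene[ib],
                                       score = 900L, stringsAsFactors = FALSE))
    }
  }
  edges <- rbind(edges,
                 data.frame(protein1 = "DECOY1", protein2 = "DECOY2",
                            score = 400L, stringsAsFactors = FALSE))
  annot <- data.frame(variant_id = cohort$variants$variant_id,
                      chrom = cohort$variants$chrom,
                      pos = cohort$variants$pos,
                      gene = gene, region = region, stringsAsFactors = FALSE)
  utils::write.table(annot, paths["annot"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, paths["ppi"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
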