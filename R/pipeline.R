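#' Configuration for a full two-stage pipeline run
#'
#' @param vcf,pheno,annot,ppi Input file paths (genotype VCF, phenotype
#'   TSV, variant annotation TSV, PPI edge TSV).
#' @param out_dir Output directory, created if needed.
#' @param thresholds A [qc_thresholds()].
#' @param gwas_alpha Genome-wide significance threshold for the Manhattan
#'   reference line (default 5e-8).
#' @param nominal_alpha Stage-1 candidate / stage-2 familywise level
#'   (default 0.05).
#' @param min_ppi_score Minimum PPI confidence (default 0.700).
#' @param contrast Additive-model contrast (see [additive_test()]).
#' @param ld_pairs Optional data frame (`variant_a`, `variant_b`) of loci
#'   whose LD should be tabulated.
#' @param plot Write the Manhattan PNG as well as its TSV?
#' @param seed Integer seed recorded in the run summary (the analysis
#'   itself is deterministic).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, pheno, annot, ppi, out_dir,
                            thresholds = qc_thresholds(),
                            gwas_alpha = 5e-8, nominal_alpha = 0.05,
                            min_ppi_score = 0.700, contrast = "I_vs_III",
                            ld_pairs = NULL, plot = FALSE, seed = 1) {
  stopifnot(gwas_alpha > 0, gwas_alpha < 1,
            nominal_alpha > 0, nominal_alpha < 1)
  structure(list(vcf = vcf, pheno = pheno, annot = annot, ppi = ppi,
                 out_dir = out_dir, thresholds = thresholds,
                 gwas_alpha = gwas_alpha, nominal_alpha = nominal_alpha,
                 min_ppi_score = min_ppi_score, contrast = contrast,
                 ld_pairs = ld_pairs, plot = plot, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `thresholds` mapping is passed to [qc_thresholds()].
#'
#' @param path YAML file path.
#' @param ... Overrides applied after the file is read.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$thresholds)) y$thresholds <- do.call(qc_thresholds, y$thresholds)
  if (!is.null(y$ld_pairs)) y$ld_pairs <- as.data.frame(y$ld_pairs)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  do.call(pipeline_config, y)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full two-stage association pipeline
#'
#' Executes QC, the single-SNP allelic scan, Manhattan export, exonic
#' candidate selection, PPI-guided pairing and the SNP-pair scan, writing
#' every table plus a machine-readable run summary into the output
#' directory. A failing stage aborts with the stage name; tables written
#' before the failure are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the run `summary` and the main tables
#'   (`qc_report`, `assoc`, `candidates`, `pairs`, `pair_results`,
#'   `ld`). Files written: `qc_report.tsv`, `assoc.tsv`, `manhattan.tsv`
#'   (+ `manhattan.png` if `plot`), `candidates.tsv`, `snp_pairs.tsv`,
#'   `pair_results.tsv`, `ld.tsv` (if requested), `run_summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- stage("read_inputs", {
    g <- read_genotype_vcf(config$vcf)
    list(genotypes = g$genotypes, variants = g$variants,
         phenotypes = read_phenotypes(config$pheno),
         annotation = read_annotation(config$annot))
  })

  qc <- stage("qc", apply_qc(inputs$genotypes, inputs$variants,
                             config$thresholds, inputs$phenotypes))
  write_tsv(qc$report, file.path(config$out_dir, "qc_report.tsv"))

  phen_kept <- inputs$phenotypes[
    inputs$phenotypes$sample_id %in% rownames(qc$genotypes), ]
  assoc <- stage("run_gwas", run_gwas(qc$genotypes, phen_kept, qc$variants))
  write_tsv(assoc, file.path(config$out_dir, "assoc.tsv"))

  stage1_threshold <- bonferroni(config$nominal_alpha, nrow(assoc))
  stage("manhattan_export", manhattan_export(
    assoc, file.path(config$out_dir, "manhattan.tsv"),
    out_plot = if (config$plot) file.path(config$out_dir, "manhattan.png"),
    gwas_threshold = config$gwas_alpha,
    bonferroni_threshold = stage1_threshold))

  ld <- NULL
  if (!is.null(config$ld_pairs)) {
    ld <- stage("ld", ld_table(qc$genotypes, config$ld_pairs,
                               phenotypes = phen_kept))
    write_tsv(ld, file.path(config$out_dir, "ld.tsv"))
  }

  candidates <- stage("select_candidates",
                      select_candidates(assoc, inputs$annotation,
                                        config$nominal_alpha))
  write_tsv(candidates, file.path(config$out_dir, "candidates.tsv"))

  edges <- stage("load_ppi_edges",
                 load_ppi_edges(config$ppi, config$min_ppi_score))
  pairs <- stage("build_snp_pairs", build_snp_pairs(candidates, edges))
  write_tsv(pairs, file.path(config$out_dir, "snp_pairs.tsv"))

  pair_results <- NULL
  stage2_threshold <- NA_real_
  if (nrow(pairs) > 0) {
    pair_results <- stage("pair_scan",
                          pair_scan(pairs, qc$genotypes, qc$variants,
                                    phen_kept, assoc,
                                    alpha = config$nominal_alpha,
                                    contrast = config$contrast))
    write_tsv(pair_results, file.path(config$out_dir, "pair_results.tsv"))
    stage2_threshold <- attr(pair_results, "bonferroni_threshold")
  }

  summary <- list(
    seed = config$seed,
    n_samples_in = nrow(inputs$genotypes),
    n_samples_removed = length(qc$samples_removed),
    qc = as.list(qc$report),
    n_variants_tested = nrow(assoc),
    stage1_bonferroni = stage1_threshold,
    gwas_threshold = config$gwas_alpha,
    n_nominal_significant = sum(assoc$p < config$nominal_alpha),
    n_candidates = nrow(candidates),
    n_ppi_edges = nrow(edges),
    n_pairs_tested = if (is.null(pair_results)) 0L else nrow(pair_results),
    stage2_bonferroni = stage2_threshold,
    n_pairs_significant = if (is.null(pair_results)) 0L
                          else sum(pair_results$passes_bonferroni),
    contrast = config$contrast
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, qc_report = qc$report, assoc = assoc,
                 candidates = candidates, pairs = pairs,
                 pair_results = pair_results, ld = ld))
}
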