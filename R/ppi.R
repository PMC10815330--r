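#' Select stage-2 candidate variants
#'
#' Keeps exonic variants with a nominally significant allelic test
#' (`p < alpha`) and records each one's risk allele (the direction with
#' odds ratio above 1). Variants absent from the annotation are dropped
#' with a warning.
#'
#' @param results A [run_gwas()] table.
#' @param annotation Annotation data frame (`variant_id`, `gene`, `region`).
#' @param alpha Nominal significance level (default 0.05).
#' @return Data frame of candidates: `variant_id`, `gene`, `region`,
#'   `risk_allele`, `protective_allele`, `or_risk`, `p`.
#' @export
select_candidates <- function(results, annotation, alpha = 0.05) {
  m <- match(results$variant_id, annotation$variant_id)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " variants without annotation were excluded")
  }
  ann_gene <- annotation$gene[m]
  ann_region <- annotation$region[m]
  keep <- !is.na(m) & ann_region == "exon" & results$p < alpha &
    !is.na(results$or) & results$or != 1
  risk_is_effect <- results$or[keep] > 1
  data.frame(
    variant_id = results$variant_id[keep],
    gene = ann_gene[keep],
    region = ann_region[keep],
    pos = results$pos[keep],
    risk_allele = ifelse(risk_is_effect, results$effect_allele[keep],
                         results$other_allele[keep]),
    protective_allele = ifelse(risk_is_effect, results$other_allele[keep],
                               results$effect_allele[keep]),
    or_risk = ifelse(risk_is_effect, results$or[keep], results$or_other[keep]),
    p = results$p[keep],
    stringsAsFactors = FALSE
  )
}

#' Load a protein-protein interaction edge table
#'
#' Reads a STRING-export-style TSV (`protein1`, `protein2`, `score`).
#' Scores above 1 are taken to be on the 0-999 integer scale and divided
#' by 1000; scores already in \[0, 1\] pass through. Self-edges are
#' dropped, reversed duplicates collapse to one undirected edge (keeping
#' the highest score), and edges scoring below `min_score` are removed.
#'
#' @param path TSV path.
#' @param min_score Minimum retained confidence (default 0.700; an edge at
#'   exactly the threshold is kept).
#' @return Data frame of class `ppi_edges`: `gene_a`, `gene_b` (sorted so
#'   `gene_a < gene_b`), `score`.
#' @export
load_ppi_edges <- function(path, min_score = 0.700) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("protein1", "protein2", "score")
  if (!all(req %in% names(raw)))
    stop("PPI file must have columns: ", paste(req, collapse = ", "))
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- is.na(score) | raw$protein1 == "" | raw$protein2 == ""
  if (any(bad))
    stop("malformed PPI rows at lines: ",
         paste(utils::head(which(bad) + 1L, 5), collapse = ", "))
  score <- ifelse(score > 1, score / 1000, score)
  if (any(score < 0 | score > 1))
    stop("PPI scores outside [0, 1] after rescaling")
  ga <- pmin(raw$protein1, raw$protein2)
  gb <- pmax(raw$protein1, raw$protein2)
  keep <- ga != gb
  edges <- data.frame(gene_a = ga[keep], gene_b = gb[keep],
                      score = score[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$gene_a, edges$gene_b, -edges$score), ]
  edges <- edges[!duplicated(edges[c("gene_a", "gene_b")]), ]
  edges <- edges[edges$score >= min_score, ]
  rownames(edges) <- NULL
  class(edges) <- c("ppi_edges", "data.frame")
  edges
}

#' Pair candidate variants across PPI edges
#'
#' For every edge whose two genes each host at least one candidate
#' variant, emits the Cartesian product of candidates across the two
#' genes. Ordering is canonical (gene pair lexicographically, then variant
#' positions), so the output does not depend on input row order.
#'
#' @param candidates A [select_candidates()] table.
#' @param edges A [load_ppi_edges()] table.
#' @return Data frame of SNP pairs: `variant_a`, `variant_b`, `gene_a`,
#'   `gene_b`, `edge_score`.
#' @export
build_snp_pairs <- function(candidates, edges) {
  by_gene <- split(candidates, candidates$gene)
  out <- list()
  for (i in seq_len(nrow(edges))) {
    ca <- by_gene[[edges$gene_a[i]]]
    cb <- by_gene[[edges$gene_b[i]]]
    if (is.null(ca) || is.null(cb)) next
    ca <- ca[order(ca$pos, ca$variant_id), ]
    cb <- cb[order(cb$pos, cb$variant_id), ]
    grid <- expand.grid(ia = seq_len(nrow(ca)), ib = seq_len(nrow(cb)))
    grid <- grid[order(grid$ia, grid$ib), ]
    out[[length(out) + 1L]] <- data.frame(
      variant_a = ca$variant_id[grid$ia],
      variant_b = cb$variant_id[grid$ib],
      gene_a = edges$gene_a[i],
      gene_b = edges$gene_b[i],
      edge_score = edges$score[i],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(variant_a = character(0), variant_b = character(0),
                      gene_a = character(0), gene_b = character(0),
                      edge_score = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  # stable sort on the gene pair keeps the within-edge position ordering
  res <- res[order(res$gene_a, res$gene_b, method = "radix"), ]
  rownames(res) <- NULL
  res
}
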