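#' Genotype matrix conventions
#'
#' Throughout the package a genotype matrix is an integer matrix with one row
#' per sample and one column per variant. Entries are the dosage of the ALT
#' allele (0, 1 or 2); missing calls are `NA`. Row names are sample ids,
#' column names variant ids. Variant metadata travels alongside in a
#' `variants` data frame with columns `variant_id`, `chrom`, `pos`, `ref`,
#' `alt` (and, after annotation, `gene` and `region`).
#'
#' @name genotype-matrix
#' @keywords internal
NULL

#' Read a genotype matrix from a VCF file
#'
#' Parses biallelic diploid GT calls into a samples-by-variants dosage
#' matrix (ALT-allele dosage, `NA` for missing). Multiallelic records are
#' rejected.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @return A list with elements `genotypes` (integer matrix, see
#'   [genotype-matrix]) and `variants` (data frame with `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`).
#' @export
read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE)))
    stop("multiallelic records are not supported: ",
         paste(utils::head(fix$ID[grepl(",", fix$ALT, fixed = TRUE)], 3),
               collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # unify phased/unphased separators, count ALT alleles
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = nrow(gt_clean), ncol = ncol(gt_clean))
  dos[gt_clean == "0/0"] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean == "1/1"] <- 2L
  bad <- !is.na(gt_clean) & gt_clean != "./." & is.na(dos) &
    !(gt_clean %in% c("0/0", "0/1", "1/0", "1/1"))
  if (any(bad))
    stop("unparseable GT calls, e.g. ", gt_clean[which(bad)[1]])
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  geno <- t(dos)
  rownames(geno) <- colnames(gt)
  colnames(geno) <- ids
  variants <- data.frame(
    variant_id = ids,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    stringsAsFactors = FALSE
  )
  list(genotypes = geno, variants = variants)
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal, deterministic VCFv4.2 text file carrying GT calls only
#' (`./.` for missing). The header contains no date or host information, so
#' identical inputs produce byte-identical files.
#'
#' @param genotypes Samples-by-variants dosage matrix (see [genotype-matrix]).
#' @param variants Variant data frame (`variant_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, variants, path) {
  stopifnot(ncol(genotypes) == nrow(variants))
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haplopair",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(j) {
    calls <- gt_codes[as.character(genotypes[, j])]
    calls[is.na(calls)] <- "./."
    paste(c(variants$chrom[j], variants$pos[j], variants$variant_id[j],
            variants$ref[j], variants$alt[j], ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' @param path TSV with columns `sample_id` and `status` (values `case` or
#'   `control`).
#' @return Data frame with those two columns.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "status")
  if (!all(req %in% names(ph)))
    stop("phenotype file must have columns: ", paste(req, collapse = ", "))
  bad <- !ph$status %in% c("case", "control")
  if (any(bad))
    stop("invalid status values: ", paste(unique(ph$status[bad]), collapse = ", "))
  ph[req]
}

#' Read a variant annotation table
#'
#' @param path TSV with columns `variant_id`, `chrom`, `pos`, `gene`,
#'   `region` (region in `exon`, `intron`, `intergenic`).
#' @return Data frame with those columns.
#' @export
read_annotation <- function(path) {
  an <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "gene", "region")
  if (!all(req %in% names(an)))
    stop("annotation file must have columns: ", paste(req, collapse = ", "))
  bad <- !an$region %in% c("exon", "intron", "intergenic")
  if (any(bad))
    stop("invalid region values: ", paste(unique(an$region[bad]), collapse = ", "))
  an[req]
}

# Case/control row masks, validated against the genotype matrix.
split_phenotypes <- function(genotypes, phenotypes) {
  missing_ph <- setdiff(rownames(genotypes), phenotypes$sample_id)
  if (length(missing_ph))
    stop("samples without phenotype: ", paste(utils::head(missing_ph, 3), collapse = ", "))
  status <- phenotypes$status[match(rownames(genotypes), phenotypes$sample_id)]
  list(case = status == "case", control = status == "control")
}

# TRUE for chromosome labels 1..22, with or without a "chr" prefix.
is_autosome <- function(chrom) {
  stripped <- sub("^chr", "", as.character(chrom))
  stripped %in% as.character(1:22)
}
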