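#' Read and write cohort tables
#'
#' Plain-text interchange for the pipeline's tabular inputs and outputs.
#' Genotypes travel as a TSV with individuals in rows (`individual_id`
#' column plus one 0/1/2/NA dosage column per SNP) and an optional SNP
#' metadata TSV (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`).
#' Summary statistics and harmonized instruments use the column layouts
#' produced by [gwas()] and [harmonize()], so an MR analysis can start from
#' externally computed summary files.
#'
#' @param path File path.
#' @param snp_info_path Optional SNP metadata TSV.
#' @return `read_genotypes()` a genotype table; the other readers plain
#'   tibbles; writers return their input invisibly.
#' @name bimr_io
NULL

#' @rdname bimr_io
#' @export
read_genotypes <- function(path, snp_info_path = NULL) {
  calls <- readr::read_tsv(path, show_col_types = FALSE)
  info <- if (!is.null(snp_info_path)) {
    readr::read_tsv(snp_info_path, show_col_types = FALSE)
  }
  as_geno_tbl(calls, info)
}

#' @rdname bimr_io
#' @param g A genotype table.
#' @export
write_genotypes <- function(g, path, snp_info_path = NULL) {
  stopifnot(inherits(g, "geno_tbl"))
  readr::write_tsv(as_tibble(g), path)
  if (!is.null(snp_info_path)) readr::write_tsv(snp_info(g), snp_info_path)
  invisible(g)
}

#' @rdname bimr_io
#' @param stats A [gwas()] summary-statistics tibble.
#' @export
write_summary_stats <- function(stats, path) {
  readr::write_tsv(as_tibble(stats), path)
  invisible(stats)
}

#' @rdname bimr_io
#' @export
read_summary_stats <- function(path) {
  stats <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("snp_id", "beta", "se", "p")
  miss <- setdiff(need, names(stats))
  if (length(miss)) {
    abort(paste("summary-statistics file missing column(s):",
                paste(miss, collapse = ", ")))
  }
  if (!"status" %in% names(stats)) stats$status <- "ok"
  stats
}

#' @rdname bimr_io
#' @export
read_harmonized <- function(path) {
  h <- readr::read_tsv(path, show_col_types = FALSE)
  h <- check_harmonized(h, 1L, "read_harmonized")
  structure(h, class = c("harmonized_instruments", class(h)))
}

#' Read genotypes from a VCF file
#'
#' Converts the GT field of a VCF into an additive dosage table (count of
#' ALT alleles, which becomes the effect allele). Multiallelic records are
#' dropped with a warning. Requires the `vcfR` package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return A genotype table.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the `vcfR` package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warn(sprintf("dropping %d multiallelic record(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dose <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_real_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
  })
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  calls <- t(dose)
  colnames(calls) <- ids
  info <- tibble(snp_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                 effect_allele = fix$ALT, other_allele = fix$REF)
  as_geno_tbl(calls, info)
}
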