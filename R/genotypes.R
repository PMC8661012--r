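#' Genotype tables
#'
#' A genotype table (`geno_tbl`) is a tibble with one row per individual: an
#' `individual_id` character column followed by one numeric column per SNP
#' holding additive dosages in \{0, 1, 2\} of the effect allele (`NA` =
#' missing call). Per-SNP metadata (chromosome, position, alleles, simulated
#' role) travels in the `snp_info` attribute, and quality-control history in
#' the `qc` attribute, so a table can be piped through the QC filters and
#' interrogated afterwards with [qc_report()].
#'
#' @param calls A data frame or matrix of dosages, individuals in rows. If a
#'   data frame contains an `individual_id` column it is used; otherwise ids
#'   `ind_0001, ...` are generated.
#' @param snp_info Optional tibble with one row per SNP column and at least a
#'   `snp_id` column; `chrom`, `pos`, `effect_allele`, `other_allele` are
#'   filled with defaults when absent.
#' @return A `geno_tbl`.
#' @examples
#' g <- as_geno_tbl(data.frame(rs1 = c(0, 1, 2), rs2 = c(1, 1, 0)))
#' snp_info(g)
#' @export
as_geno_tbl <- function(calls, snp_info = NULL) {
  if (is.matrix(calls)) {
    ids <- rownames(calls) %||% sprintf("ind_%04d", seq_len(nrow(calls)))
    calls <- as_tibble(calls, .name_repair = "minimal")
    calls$individual_id <- ids
  }
  calls <- as_tibble(calls)
  if (!"individual_id" %in% names(calls)) {
    calls$individual_id <- sprintf("ind_%04d", seq_len(nrow(calls)))
  }
  calls <- dplyr::relocate(calls, "individual_id")
  snp_ids <- setdiff(names(calls), "individual_id")
  if (anyDuplicated(snp_ids)) abort("SNP ids must be unique")
  if (anyDuplicated(calls$individual_id)) abort("individual ids must be unique")
  dose <- as.matrix(calls[snp_ids])
  if (length(dose) && !all(dose[!is.na(dose)] %in% c(0, 1, 2))) {
    abort("genotype calls must be 0, 1, 2 or NA")
  }
  if (is.null(snp_info)) snp_info <- tibble(snp_id = snp_ids)
  snp_info <- as_tibble(snp_info)
  if (!"snp_id" %in% names(snp_info)) abort("`snp_info` needs a `snp_id` column")
  if (!identical(sort(snp_info$snp_id), sort(snp_ids))) {
    abort("`snp_info$snp_id` must match the SNP columns of `calls`")
  }
  snp_info <- snp_info[match(snp_ids, snp_info$snp_id), ]
  if (!"chrom" %in% names(snp_info)) snp_info$chrom <- 1L
  if (!"pos" %in% names(snp_info)) {
    snp_info$pos <- stats::ave(seq_along(snp_ids), snp_info$chrom,
                               FUN = function(i) seq_along(i) * 10000L)
  }
  if (!"effect_allele" %in% names(snp_info)) snp_info$effect_allele <- "A"
  if (!"other_allele" %in% names(snp_info)) snp_info$other_allele <- "G"
  new_geno_tbl(calls, snp_info, qc = empty_qc_log())
}

new_geno_tbl <- function(calls, snp_info, qc) {
  structure(calls,
            snp_info = snp_info,
            qc = qc,
            class = c("geno_tbl", class(tibble())))
}

empty_qc_log <- function() {
  list(
    steps = tibble(step = character(), axis = character(),
                   n_in = integer(), n_removed = integer(),
                   threshold = character()),
    removed = tibble(id = character(), axis = character(), reason = character())
  )
}

#' @rdname as_geno_tbl
#' @param g A `geno_tbl`.
#' @export
snp_info <- function(g) attr(g, "snp_info")

#' @rdname as_geno_tbl
#' @export
geno_matrix <- function(g) {
  stopifnot(inherits(g, "geno_tbl"))
  m <- as.matrix(as_tibble(g)[setdiff(names(g), "individual_id")])
  rownames(m) <- g$individual_id
  storage.mode(m) <- "double"
  m
}

#' @export
print.geno_tbl <- function(x, ...) {
  cat(sprintf("# Genotype table: %d individuals x %d SNPs\n",
              nrow(x), ncol(x) - 1L))
  qc <- attr(x, "qc")
  if (!is.null(qc) && nrow(qc$steps)) {
    cat(sprintf("# QC steps applied: %s\n", paste(qc$steps$step, collapse = " -> ")))
  }
  print(as_tibble(x), ...)
  invisible(x)
}

# rebuild a geno_tbl after dropping individuals/SNPs, appending a QC step
subset_geno <- function(g, keep_ind = NULL, keep_snp = NULL,
                        step, axis, reason, threshold) {
  info <- snp_info(g)
  qc <- attr(g, "qc")
  tb <- as_tibble(g)
  if (axis == "individual") {
    n_in <- nrow(tb)
    dropped <- tb$individual_id[!keep_ind]
    tb <- tb[keep_ind, , drop = FALSE]
  } else {
    snp_ids <- info$snp_id
    n_in <- length(snp_ids)
    dropped <- snp_ids[!keep_snp]
    tb <- tb[c("individual_id", snp_ids[keep_snp])]
    info <- info[keep_snp, , drop = FALSE]
  }
  qc$steps <- dplyr::bind_rows(qc$steps, tibble(
    step = step, axis = axis, n_in = n_in,
    n_removed = length(dropped), threshold = threshold))
  if (length(dropped)) {
    qc$removed <- dplyr::bind_rows(qc$removed, tibble(
      id = dropped, axis = axis, reason = reason))
  }
  new_geno_tbl(tb, info, qc)
}
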