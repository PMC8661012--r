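#' Genotype quality-control filters
#'
#' The QC cascade applied before instrument discovery, mirroring standard
#' GWAS practice: drop individuals with a high fraction of missing calls,
#' drop SNPs with low call rate, drop SNPs deviating from Hardy-Weinberg
#' equilibrium, then prune one member of each highly correlated SNP pair.
#' Each filter takes and returns a genotype table, so the stages chain with
#' the pipe; every removal is recorded (with the first triggering stage as
#' its single reason) and summarized by [qc_report()].
#'
#' Threshold semantics follow the conventional strict inequalities: an
#' individual is removed when its missing fraction is strictly greater than
#' `max_missing`; a SNP is removed when its call rate is strictly below
#' `min_call_rate`; a SNP is pruned when a within-window pair has r^2
#' strictly above `r2_threshold`.
#'
#' @param g A genotype table.
#' @param max_missing Maximum tolerated per-individual missing fraction
#'   (default 0.05).
#' @return The filtered genotype table (QC history updated).
#' @name qc_filters
NULL

#' @rdname qc_filters
#' @export
filter_individual_missingness <- function(g, max_missing = 0.05) {
  stopifnot(inherits(g, "geno_tbl"))
  check_rate(max_missing, "max_missing")
  m <- geno_matrix(g)
  if (!length(m)) abort("empty genotype table")
  frac <- rowMeans(is.na(m))
  subset_geno(g, keep_ind = frac <= max_missing, step = "individual_missingness",
              axis = "individual", reason = "individual_missingness",
              threshold = sprintf("missing > %g", max_missing))
}

#' @rdname qc_filters
#' @param min_call_rate Minimum tolerated per-SNP call rate, computed over
#'   the currently retained individuals (default 0.97).
#' @export
filter_snp_call_rate <- function(g, min_call_rate = 0.97) {
  stopifnot(inherits(g, "geno_tbl"))
  if (!is.numeric(min_call_rate) || min_call_rate <= 0 || min_call_rate > 1) {
    abort("`min_call_rate` must lie in (0, 1]")
  }
  m <- geno_matrix(g)
  if (!length(m)) abort("empty genotype table")
  rate <- colMeans(!is.na(m))
  subset_geno(g, keep_snp = rate >= min_call_rate, step = "snp_call_rate",
              axis = "snp", reason = "call_rate",
              threshold = sprintf("call rate < %g", min_call_rate))
}

#' @rdname qc_filters
#' @param alpha Significance level of the Hardy-Weinberg exact test below
#'   which a SNP is removed; default 1e-6, common GWAS practice.
#' @param midp Passed to [hwe_exact_test()].
#' @export
filter_hwe <- function(g, alpha = 1e-6, midp = FALSE) {
  stopifnot(inherits(g, "geno_tbl"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1)")
  }
  counts <- genotype_counts(g)
  if (!nrow(counts)) abort("empty genotype table")
  p <- hwe_exact_test(counts$n_hom_ref, counts$n_het, counts$n_hom_alt,
                      midp = midp)
  subset_geno(g, keep_snp = p >= alpha, step = "hwe",
              axis = "snp", reason = "hwe",
              threshold = sprintf("HWE exact p < %g", alpha))
}

#' Squared dosage correlation between two SNPs
#'
#' Composite (genotype-dosage) linkage disequilibrium: the squared Pearson
#' correlation of additive genotype codes over pairwise-complete
#' observations. This is deterministic and phase-free, matching PLINK's
#' dosage-correlation mode rather than EM-phased haplotype r^2.
#'
#' @param g1,g2 Numeric dosage vectors of equal length.
#' @return r^2 in `[0, 1]`.
#' @export
pairwise_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) abort("genotype vectors must have equal length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) abort("need at least 2 pairwise-complete observations")
  if (var(g1[ok]) == 0 || var(g2[ok]) == 0) {
    abort("correlation undefined for a constant genotype vector")
  }
  cor(g1[ok], g2[ok])^2
}

#' @rdname qc_filters
#' @param r2_threshold Pairs with squared dosage correlation strictly above
#'   this are pruned (default 0.8).
#' @param window_snps,step_snps Sliding-window size and step, in SNPs. The
#'   window slides within each chromosome over position-sorted SNPs; within a
#'   window the later-positioned member of an offending pair is dropped
#'   (deterministic, index-stable tie-break). `window_snps = Inf` performs
#'   the full all-pairs scan.
#' @export
ld_prune <- function(g, r2_threshold = 0.8, window_snps = 50, step_snps = 5) {
  stopifnot(inherits(g, "geno_tbl"))
  if (!is.numeric(r2_threshold) || r2_threshold <= 0 || r2_threshold > 1) {
    abort("`r2_threshold` must lie in (0, 1]")
  }
  if (!is.infinite(window_snps) && window_snps < 2) abort("`window_snps` must be >= 2")
  if (step_snps < 1) abort("`step_snps` must be >= 1")
  info <- snp_info(g)
  m <- geno_matrix(g)
  if (!length(m)) abort("empty genotype table")
  drop <- logical(ncol(m))
  names(drop) <- colnames(m)
  for (chr in unique(info$chrom)) {
    idx <- which(info$chrom == chr)
    if (is.unsorted(info$pos[idx])) {
      abort(sprintf("SNP positions on chromosome %s are not sorted; sort before pruning", chr))
    }
    w <- if (is.infinite(window_snps)) length(idx) else as.integer(window_snps)
    starts <- if (length(idx) <= w) 1L else
      unique(c(seq(1L, length(idx) - w + 1L, by = as.integer(step_snps)),
               length(idx) - w + 1L))
    for (s in starts) {
      win <- idx[s:min(s + w - 1L, length(idx))]
      for (a in seq_along(win)) {
        ia <- win[a]
        if (drop[ia]) next
        for (b in seq_len(a - 1L)) {
          ib <- win[b]
          if (drop[ib]) next
          r2 <- tryCatch(pairwise_r2(m[, ib], m[, ia]), error = function(e) NA_real_)
          if (!is.na(r2) && r2 > r2_threshold) {
            drop[ia] <- TRUE   # later-positioned member goes
            break
          }
        }
      }
    }
  }
  subset_geno(g, keep_snp = !drop, step = "ld_prune",
              axis = "snp", reason = "ld_pruned",
              threshold = sprintf("r2 > %g (window %s, step %d)",
                                  r2_threshold,
                                  if (is.infinite(window_snps)) "all" else window_snps,
                                  as.integer(step_snps)))
}

#' Run the full QC cascade
#'
#' Applies the four filters in the conventional order — individual
#' missingness, SNP call rate, Hardy-Weinberg, LD pruning — with their
#' default (or supplied) thresholds.
#'
#' @param g A genotype table.
#' @inheritParams qc_filters
#' @inheritParams filter_hwe
#' @param hwe_alpha Hardy-Weinberg removal level.
#' @return The filtered genotype table; inspect removals with [qc_report()].
#' @export
qc_pipeline <- function(g, max_missing = 0.05, min_call_rate = 0.97,
                        hwe_alpha = 1e-6, r2_threshold = 0.8,
                        window_snps = 50, step_snps = 5) {
  g |>
    filter_individual_missingness(max_missing) |>
    filter_snp_call_rate(min_call_rate) |>
    filter_hwe(hwe_alpha) |>
    ld_prune(r2_threshold, window_snps, step_snps)
}

#' Quality-control report
#'
#' Summarizes the filters applied to a genotype table: counts in and out per
#' axis, removals per stage with thresholds, and the identity and (single,
#' first-triggering) reason of every removed individual and SNP.
#'
#' @param g A genotype table that has passed through one or more filters.
#' @return A `qc_report` list with tibbles `summary`, `steps`, `removed`.
#' @export
qc_report <- function(g) {
  stopifnot(inherits(g, "geno_tbl"))
  qc <- attr(g, "qc")
  removed <- qc$removed
  n_ind_removed <- sum(removed$axis == "individual")
  n_snp_removed <- sum(removed$axis == "snp")
  summary <- tibble(
    axis = c("individual", "snp"),
    n_in = c(nrow(g) + n_ind_removed, ncol(g) - 1L + n_snp_removed),
    n_removed = c(n_ind_removed, n_snp_removed),
    n_out = c(nrow(g), ncol(g) - 1L))
  structure(list(summary = summary, steps = qc$steps, removed = removed),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Quality-control report\n")
  print(x$summary)
  if (nrow(x$steps)) {
    cat("\nStages (in order applied):\n")
    print(x$steps)
  }
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) x$steps

#' @export
glance.qc_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "axis",
                     values_from = c("n_in", "n_removed", "n_out"))
}
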