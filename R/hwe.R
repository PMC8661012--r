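#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test for a biallelic SNP. Conditional on the
#' observed allele counts, the number of heterozygotes under Hardy-Weinberg
#' equilibrium follows
#' \deqn{P(N_{het} = h) = \frac{n!\, 2^h\, n_A!\, n_B!}{n_{AA}!\, h!\, n_{BB}!\, (2n)!}}
#' and the p-value sums the probabilities of all heterozygote counts no more
#' probable than the observed one. Probabilities are computed by the stable
#' ratio recurrence across the admissible heterozygote counts (same parity as
#' the minor-allele count). A mid-p variant (half weight on the observed
#' configuration) is available but off by default.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (vectors are accepted and
#'   recycled to a common length).
#' @param midp Use the mid-p correction.
#' @return Vector of p-values in (0, 1]. Monomorphic SNPs return exactly 1.
#' @examples
#' hwe_exact_test(57, 78, 13)
#' hwe_exact_test(0, 100, 0)  # gross heterozygote excess
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt, midp = FALSE) {
  k <- max(length(n_hom_ref), length(n_het), length(n_hom_alt))
  n_hom_ref <- rep_len(n_hom_ref, k)
  n_het <- rep_len(n_het, k)
  n_hom_alt <- rep_len(n_hom_alt, k)
  counts <- cbind(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  if (any(rowSums(counts) < 1)) abort("total genotype count must be at least 1")
  vapply(seq_len(k), function(i) {
    hwe_exact_one(counts[i, 1], counts[i, 2], counts[i, 3], midp)
  }, numeric(1))
}

hwe_exact_one <- function(aa, ab, bb, midp) {
  n <- aa + ab + bb
  nA <- 2 * aa + ab   # allele A count
  nB <- 2 * bb + ab
  rare <- min(nA, nB)
  if (rare == 0) return(1)   # monomorphic: single attainable configuration
  # admissible het counts share the parity of the rare allele count
  h0 <- rare %% 2
  hs <- seq.int(h0, rare, by = 2L)
  probs <- numeric(length(hs))
  # unnormalized start at the smallest admissible het count, then recur:
  # P(h+2)/P(h) = 4 * n_AA(h) * n_BB(h) / ((h+2)(h+1))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (idx in seq_len(length(hs) - 1L)) {
      h <- hs[idx]
      naa <- (nA - h) / 2
      nbb <- (nB - h) / 2
      probs[idx + 1L] <- probs[idx] * 4 * naa * nbb / ((h + 2) * (h + 1))
      # rescale to dodge overflow on large tables
      if (probs[idx + 1L] > 1e280) probs <- probs / 1e280
    }
  }
  probs <- probs / sum(probs)
  obs <- match(ab, hs)
  if (is.na(obs)) abort("heterozygote count inconsistent with allele counts")
  p_obs <- probs[obs]
  inc <- probs <= p_obs * (1 + 1e-12)
  p <- if (midp) sum(probs[inc]) - 0.5 * p_obs else sum(probs[inc])
  min(p, 1)
}

#' Genotype counts per SNP
#'
#' Tallies hom-ref / het / hom-alt calls (effect-allele dosage 0/1/2) for
#' each SNP over non-missing entries.
#'
#' @param g A genotype table.
#' @return A tibble: `snp_id`, `n_hom_ref`, `n_het`, `n_hom_alt`, `n_called`.
#' @export
genotype_counts <- function(g) {
  m <- geno_matrix(g)
  tibble(
    snp_id = colnames(m),
    n_hom_ref = colSums(m == 0, na.rm = TRUE),
    n_het = colSums(m == 1, na.rm = TRUE),
    n_hom_alt = colSums(m == 2, na.rm = TRUE)) |>
    dplyr::mutate(n_called = .data$n_hom_ref + .data$n_het + .data$n_hom_alt)
}
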