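#' Simulation configuration for synthetic MR cohorts
#'
#' Describes a cohort with the causal structure a one-sample Mendelian
#' randomization analysis assumes: a continuous exposure (platelet-count-like,
#' mean-centred in simulation units) driven additively by a block of
#' instrument SNPs, a binary (or continuous) outcome carrying the causal
#' exposure effect plus optional direct (pleiotropic) SNP effects and a block
#' of outcome-specific instrument SNPs, and shared confounders influencing
#' both traits.
#'
#' Under `direction = "forward"` the exposure is generated first:
#' \deqn{X_i = \sum_j \beta_{Xj} g_{ij} + \gamma^T C_i + \epsilon_i}
#' and a binary outcome follows
#' \deqn{Y_i \sim Bern(logit^{-1}(c + \theta X_i + \sum_j \alpha_j g_{ij} +
#'   \sum_k b_k g_{ik} + \delta^T C_i))}
#' where \eqn{\alpha_j} are pleiotropic effects of the exposure instruments
#' and \eqn{b_k} direct effects of the outcome-instrument block. Under
#' `direction = "reverse"` the binary trait is generated first from its own
#' instruments and the continuous trait receives `reverse_effect` times the
#' binary trait. `outcome_kind = "continuous"` replaces the logistic link
#' with a linear model plus Gaussian noise (`outcome_noise_sd`).
#'
#' @param n_individuals,n_snps Cohort and panel sizes. SNPs beyond the two
#'   instrument blocks are causally inert ("null" SNPs).
#' @param instrument_effects Numeric vector of per-allele effects of the
#'   exposure-instrument block on the exposure (exposure units).
#' @param outcome_instrument_effects Per-allele direct effects of the
#'   outcome-instrument block on the outcome (log-odds units when binary).
#' @param pleiotropy Either a numeric vector of direct effects
#'   \eqn{\alpha_j} (one per instrument of the trait generated first), or a
#'   list `list(type = "none"|"balanced"|"directional", mean =, sd =)` drawn
#'   freshly per simulated cohort.
#' @param causal_effect The causal effect \eqn{\theta} of exposure on outcome
#'   (log-odds per exposure unit when the outcome is binary).
#' @param reverse_effect Causal effect of the binary trait on the continuous
#'   trait, used when `direction = "reverse"`.
#' @param direction Which trait is generated first (see Details).
#' @param outcome_kind `"binary"` (logistic link) or `"continuous"`.
#' @param maf Optional vector of effect-allele frequencies (one per SNP);
#'   otherwise drawn uniformly from `maf_range`.
#' @param maf_range Pair in (0, 0.5] from which MAFs are drawn.
#' @param confounders A tibble describing shared confounders (see
#'   [default_confounders()]), or `NULL` for none. Columns: `name`, `dist`
#'   (`"normal"`/`"bernoulli"`), `mean`, `sd`, `beta_exposure`,
#'   `beta_outcome`.
#' @param exposure_noise_sd,outcome_noise_sd Residual standard deviations.
#' @param outcome_intercept Intercept of the logistic outcome model; controls
#'   prevalence (default -1.1, about 25% at null covariates).
#' @param missing_rate_snp,missing_rate_individual Genotype missingness rates
#'   applied uniformly after simulation (0 = complete calls).
#' @param exposure_name,outcome_name Column names used in the phenotype table.
#' @param seed Root seed; every stage derives its own stream from it, so the
#'   same config and seed reproduce the cohort bit-for-bit.
#' @return A `sim_config` list.
#' @seealso [simulate_cohort()], [simulate_genotypes()], [simulate_traits()]
#' @export
sim_config <- function(n_individuals = 2000,
                       n_snps = NULL,
                       instrument_effects = c(0.20, 0.15, 0.25, 0.18, 0.22),
                       outcome_instrument_effects = numeric(0),
                       pleiotropy = list(type = "none"),
                       causal_effect = 0,
                       reverse_effect = 0,
                       direction = c("forward", "reverse"),
                       outcome_kind = c("binary", "continuous"),
                       maf = NULL,
                       maf_range = c(0.1, 0.5),
                       confounders = NULL,
                       exposure_noise_sd = 1,
                       outcome_noise_sd = 1,
                       outcome_intercept = -1.1,
                       missing_rate_snp = 0,
                       missing_rate_individual = 0,
                       exposure_name = "exposure",
                       outcome_name = "outcome",
                       seed = 1L) {
  direction <- match.arg(direction)
  outcome_kind <- match.arg(outcome_kind)
  n_individuals <- check_positive_count(n_individuals, "n_individuals")
  n_instr <- length(instrument_effects)
  n_out_instr <- length(outcome_instrument_effects)
  if (is.null(n_snps)) n_snps <- n_instr + n_out_instr
  n_snps <- check_positive_count(n_snps, "n_snps")
  if (n_instr + n_out_instr > n_snps) {
    abort("instrument blocks cannot exceed `n_snps`")
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair in (0, 0.5]")
  }
  if (!is.null(maf) && length(maf) != n_snps) {
    abort("`maf` must have one frequency per SNP")
  }
  check_rate(missing_rate_snp, "missing_rate_snp")
  check_rate(missing_rate_individual, "missing_rate_individual")
  if (exposure_noise_sd < 0 || outcome_noise_sd < 0) {
    abort("noise standard deviations must be non-negative")
  }
  if (is.numeric(pleiotropy)) {
    n_first <- if (direction == "forward") n_instr else n_out_instr
    if (length(pleiotropy) != n_first) {
      abort("numeric `pleiotropy` must match the first-generated instrument block length")
    }
  } else if (!is.list(pleiotropy) ||
             !pleiotropy$type %in% c("none", "balanced", "directional")) {
    abort("`pleiotropy` must be a numeric vector or list(type = none|balanced|directional, ...)")
  }
  if (!is.null(confounders)) {
    confounders <- as_tibble(confounders)
    need <- c("name", "dist", "mean", "sd", "beta_exposure", "beta_outcome")
    if (!all(need %in% names(confounders))) {
      abort(paste("`confounders` needs columns:", paste(need, collapse = ", ")))
    }
  }
  structure(list(
    n_individuals = n_individuals, n_snps = n_snps,
    instrument_effects = instrument_effects,
    outcome_instrument_effects = outcome_instrument_effects,
    pleiotropy = pleiotropy, causal_effect = causal_effect,
    reverse_effect = reverse_effect, direction = direction,
    outcome_kind = outcome_kind, maf = maf, maf_range = maf_range,
    confounders = confounders, exposure_noise_sd = exposure_noise_sd,
    outcome_noise_sd = outcome_noise_sd, outcome_intercept = outcome_intercept,
    missing_rate_snp = missing_rate_snp,
    missing_rate_individual = missing_rate_individual,
    exposure_name = exposure_name, outcome_name = outcome_name,
    seed = as.integer(seed)), class = "sim_config")
}

#' Default confounder panel
#'
#' Nine covariates shaped like the clinical panel of a hypertension cohort
#' (sex, age, fasting glucose, hematocrit, triglyceride, HDL cholesterol,
#' hemoglobin, red and white blood cell counts), with marginal means and
#' spreads typical of a middle-aged East-Asian biobank population. The
#' marginals are cosmetic; the load-bearing parts are the per-covariate
#' effects on exposure and outcome, which default to zero.
#'
#' @param beta_exposure,beta_outcome Length-9 effect vectors (recycled from
#'   length 1) of each covariate on exposure and outcome.
#' @return A tibble usable as the `confounders` field of [sim_config()].
#' @export
default_confounders <- function(beta_exposure = 0, beta_outcome = 0) {
  tb <- tibble(
    name = c("sex", "age", "fasting_glucose", "hematocrit", "triglyceride",
             "hdl_cholesterol", "hemoglobin", "rbc_count", "wbc_count"),
    dist = c("bernoulli", rep("normal", 8)),
    mean = c(0.498, 48.7, 96.5, 43.6, 117.5, 53.1, 13.95, 4.80, 6.10),
    sd = c(NA, 11.0, 21.0, 4.5, 91.4, 13.0, 1.56, 0.52, 1.58))
  tb$beta_exposure <- rep_len(beta_exposure, 9L)
  tb$beta_outcome <- rep_len(beta_outcome, 9L)
  tb
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Draws each SNP's additive dosages independently as Binomial(2, p) with p
#' the effect-allele frequency, i.e. genotype probabilities
#' \eqn{((1-p)^2, 2p(1-p), p^2)} — the Hardy-Weinberg proportions.
#'
#' @param n Number of individuals.
#' @param snp_mafs Vector of effect-allele frequencies, each in (0, 0.5].
#' @param seed Integer seed (reproducible draws).
#' @param snp_ids Optional SNP names; defaults to `snp_0001, ...`.
#' @param snp_roles Optional character vector recorded in `snp_info(g)$role`.
#' @return A [as_geno_tbl()] genotype table with no missing calls.
#' @examples
#' g <- simulate_genotypes(100, c(0.2, 0.4), seed = 7)
#' colMeans(geno_matrix(g)) / 2  # close to the MAFs
#' @export
simulate_genotypes <- function(n, snp_mafs, seed, snp_ids = NULL,
                               snp_roles = NULL) {
  n <- check_positive_count(n, "n")
  if (any(snp_mafs <= 0) || any(snp_mafs > 0.5)) {
    abort("`snp_mafs` must lie in (0, 0.5]")
  }
  m <- length(snp_mafs)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%04d", seq_len(m))
  calls <- withr::with_seed(derive_seed(seed, "genotypes"), {
    matrix(rbinom(n * m, size = 2L, prob = rep(snp_mafs, each = n)),
           nrow = n, ncol = m)
  })
  colnames(calls) <- snp_ids
  info <- tibble(snp_id = snp_ids, chrom = 1L,
                 pos = seq_len(m) * 10000L,
                 effect_allele = "A", other_allele = "G",
                 maf = snp_mafs,
                 role = snp_roles %||% rep("null", m))
  as_geno_tbl(calls, info)
}

#' Mask genotype calls at given rates
#'
#' Sets calls to `NA` independently at per-SNP and/or per-individual rates,
#' for building quality-control fixtures. The input table is not modified.
#'
#' @param g A genotype table.
#' @param snp_rates Named vector of rates (names = SNP ids), or a single
#'   unnamed rate applied to every SNP.
#' @param individual_rates Same, keyed by individual id.
#' @param seed Integer seed.
#' @return A genotype table with masked entries.
#' @export
inject_missingness <- function(g, snp_rates = NULL, individual_rates = NULL,
                               seed = 1L) {
  stopifnot(inherits(g, "geno_tbl"))
  m <- geno_matrix(g)
  resolve <- function(rates, keys, what) {
    if (is.null(rates)) return(NULL)
    for (r in rates) check_rate(r, sprintf("%s rate", what))
    if (is.null(names(rates))) {
      if (length(rates) != 1L) abort(sprintf("unnamed `%s` rates must be length 1", what))
      return(setNames(rep(rates, length(keys)), keys))
    }
    unknown <- setdiff(names(rates), keys)
    if (length(unknown)) {
      abort(sprintf("unknown %s key(s): %s", what, paste(unknown, collapse = ", ")))
    }
    rates
  }
  snp_rates <- resolve(snp_rates, colnames(m), "snp")
  individual_rates <- resolve(individual_rates, rownames(m), "individual")
  withr::with_seed(derive_seed(seed, "missingness"), {
    for (s in names(snp_rates)) {
      if (snp_rates[[s]] > 0) {
        mask <- runif(nrow(m)) < snp_rates[[s]]
        m[mask, s] <- NA_real_
      }
    }
    for (i in names(individual_rates)) {
      if (individual_rates[[i]] > 0) {
        mask <- runif(ncol(m)) < individual_rates[[i]]
        m[i, mask] <- NA_real_
      }
    }
  })
  tb <- as_tibble(m)
  tb$individual_id <- rownames(m)
  tb <- dplyr::relocate(tb, "individual_id")
  new_geno_tbl(tb, snp_info(g), attr(g, "qc"))
}

# realize pleiotropy spec into a numeric alpha vector (length J), seeded
draw_pleiotropy <- function(pleio, J, seed) {
  if (is.numeric(pleio)) return(pleio)
  switch(pleio$type,
    none = rep(0, J),
    balanced = withr::with_seed(derive_seed(seed, "pleiotropy"),
                                rnorm(J, 0, pleio$sd)),
    directional = withr::with_seed(derive_seed(seed, "pleiotropy"),
                                   rnorm(J, pleio$mean, pleio$sd %||% 0)))
}

#' Simulate exposure and outcome traits on a genotype table
#'
#' Generates the phenotype table for a simulated cohort under the causal
#' model described in [sim_config()]. Confounders (if any) are drawn per
#' individual and affect both traits, while being independent of genotype by
#' construction, so the instrumental-variable independence assumption holds.
#'
#' @param g A genotype table with at least as many SNPs as the config's
#'   instrument blocks; the first block of columns is treated as the
#'   exposure instruments, the following block as the outcome instruments.
#' @param config A [sim_config()].
#' @return A phenotype tibble: `individual_id`, exposure column, outcome
#'   column and one column per confounder. The realized generative
#'   parameters (alpha vector, confounder draw seed) are attached as the
#'   `truth` attribute.
#' @export
simulate_traits <- function(g, config) {
  stopifnot(inherits(g, "geno_tbl"), inherits(config, "sim_config"))
  G <- geno_matrix(g)
  n <- nrow(G)
  J <- length(config$instrument_effects)
  K <- length(config$outcome_instrument_effects)
  if (ncol(G) < J + K) abort("genotype table has fewer SNPs than the config's instrument blocks")
  Gx <- G[, seq_len(J), drop = FALSE]
  Gy <- if (K) G[, J + seq_len(K), drop = FALSE] else NULL

  conf <- config$confounders
  C <- NULL
  if (!is.null(conf) && nrow(conf)) {
    C <- withr::with_seed(derive_seed(config$seed, "confounders"), {
      vapply(seq_len(nrow(conf)), function(k) {
        if (conf$dist[k] == "bernoulli") rbinom(n, 1L, conf$mean[k])
        else rnorm(n, conf$mean[k], conf$sd[k])
      }, numeric(n))
    })
    colnames(C) <- conf$name
  }
  conf_x <- if (is.null(C)) 0 else drop(C %*% conf$beta_exposure)
  conf_y <- if (is.null(C)) 0 else drop(C %*% conf$beta_outcome)

  n_first <- if (config$direction == "forward") J else K
  alpha <- draw_pleiotropy(config$pleiotropy, n_first, config$seed)

  gx_eff <- drop(Gx %*% config$instrument_effects)
  gy_eff <- if (K) drop(Gy %*% config$outcome_instrument_effects) else 0

  res <- withr::with_seed(derive_seed(config$seed, "traits"), {
    if (config$direction == "forward") {
      pleio_y <- if (J) drop(Gx %*% alpha) else 0
      X <- gx_eff + conf_x + rnorm(n, 0, config$exposure_noise_sd)
      eta <- config$outcome_intercept + config$causal_effect * X +
        pleio_y + gy_eff + conf_y
      Y <- if (config$outcome_kind == "binary") {
        rbinom(n, 1L, plogis(eta))
      } else {
        config$causal_effect * X + pleio_y + gy_eff + conf_y +
          rnorm(n, 0, config$outcome_noise_sd)
      }
      list(X = X, Y = Y)
    } else {
      pleio_x <- if (K) drop(Gy %*% alpha) else 0
      eta <- config$outcome_intercept + gy_eff + conf_y
      Y <- rbinom(n, 1L, plogis(eta))
      X <- config$reverse_effect * Y + gx_eff + pleio_x + conf_x +
        rnorm(n, 0, config$exposure_noise_sd)
      list(X = X, Y = Y)
    }
  })

  pheno <- tibble(individual_id = rownames(G))
  pheno[[config$exposure_name]] <- res$X
  pheno[[config$outcome_name]] <- as.numeric(res$Y)
  if (!is.null(C)) pheno <- dplyr::bind_cols(pheno, as_tibble(C))
  attr(pheno, "truth") <- list(alpha = alpha, config = config)
  pheno
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: draws MAFs, genotypes, traits and optional
#' missingness from one [sim_config()], labelling SNP roles
#' (`exposure_instrument`, `outcome_instrument`, `null`) in the genotype
#' table's metadata.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a `geno_tbl`) and `phenotypes`
#'   (a tibble).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 500, seed = 42))
#' cohort$phenotypes
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- length(config$instrument_effects)
  K <- length(config$outcome_instrument_effects)
  mafs <- config$maf %||% withr::with_seed(
    derive_seed(config$seed, "mafs"),
    runif(config$n_snps, config$maf_range[1], config$maf_range[2]))
  roles <- c(rep("exposure_instrument", J), rep("outcome_instrument", K),
             rep("null", config$n_snps - J - K))
  g <- simulate_genotypes(config$n_individuals, mafs, seed = config$seed,
                          snp_roles = roles)
  pheno <- simulate_traits(g, config)
  if (config$missing_rate_snp > 0 || config$missing_rate_individual > 0) {
    g <- inject_missingness(
      g,
      snp_rates = if (config$missing_rate_snp > 0) config$missing_rate_snp,
      individual_rates = if (config$missing_rate_individual > 0) config$missing_rate_individual,
      seed = config$seed)
  }
  list(genotypes = g, phenotypes = pheno)
}

#' Simulate a block of SNPs in linkage disequilibrium
#'
#' Generates correlated dosages through a Gaussian copula: a latent
#' equicorrelated multivariate normal is sliced at the Hardy-Weinberg
#' genotype quantiles of each SNP's MAF. Exists to exercise the LD pruner;
#' association scans in this package simulate instruments independently.
#'
#' @param n Individuals.
#' @param mafs Effect-allele frequencies of the block members.
#' @param rho Latent pairwise correlation in `[0, 1)`.
#' @param seed Integer seed.
#' @param snp_ids Optional ids.
#' @return A genotype table.
#' @export
simulate_ld_block <- function(n, mafs, rho = 0.95, seed = 1L, snp_ids = NULL) {
  n <- check_positive_count(n, "n")
  if (any(mafs <= 0) || any(mafs > 0.5)) abort("`mafs` must lie in (0, 0.5]")
  check_rate(rho, "rho")
  m <- length(mafs)
  Z <- withr::with_seed(derive_seed(seed, "ld_block"), {
    shared <- rnorm(n)
    sqrt(rho) * matrix(shared, n, m) + sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
  })
  calls <- vapply(seq_len(m), function(j) {
    p <- mafs[j]
    q <- qnorm(cumsum(c((1 - p)^2, 2 * p * (1 - p))))
    findInterval(Z[, j], q)
  }, numeric(n))
  colnames(calls) <- snp_ids %||% sprintf("ld_snp_%03d", seq_len(m))
  as_geno_tbl(calls)
}
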