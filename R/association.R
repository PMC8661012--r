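#' Ordinary least squares with inference
#'
#' Linear regression with an intercept, returning coefficient estimates,
#' standard errors from \eqn{\hat\sigma^2 (X^T X)^{-1}}, and two-sided
#' p-values from the t reference distribution. The workhorse behind the
#' continuous-trait association scan and the F-statistic screen.
#'
#' @param y Numeric response.
#' @param design Numeric matrix or data frame of predictors (no intercept
#'   column; one is added). Rows with any missing value are dropped.
#' @return A list: `coefficients` tibble (`term`, `estimate`, `se`, `p`),
#'   `residual_variance`, `df_residual`, `n_used`, `rss`.
#' @export
fit_linear <- function(y, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- sprintf("x%d", seq_len(ncol(design)))
  }
  ok <- complete.cases(y, design)
  y <- y[ok]
  X <- cbind(`(Intercept)` = 1, design[ok, , drop = FALSE])
  if (nrow(X) < ncol(X) + 1L) abort("too few complete cases for the design")
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) abort("singular design: predictors are collinear")
  rss <- sum(fit$residuals^2)
  df <- nrow(X) - ncol(X)
  s2 <- rss / df
  Rm <- qr.R(fit$qr)
  XtX_inv <- chol2inv(Rm)
  piv <- fit$qr$pivot
  dvar <- numeric(ncol(X))
  dvar[piv] <- diag(XtX_inv)
  se <- sqrt(pmax(dvar * s2, 0))
  tstat <- fit$coefficients / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  p[se == 0] <- 0
  list(
    coefficients = tibble(term = colnames(X), estimate = unname(fit$coefficients),
                          se = unname(se), p = unname(p)),
    residual_variance = s2, df_residual = df, n_used = nrow(X), rss = rss)
}

#' Logistic regression with inference
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (25 iterations maximum, convergence tolerance 1e-8 on the
#' deviance), Wald standard errors from the observed information, and
#' two-sided normal p-values. Perfect separation raises an error;
#' non-convergence is flagged, never silent.
#'
#' @param y Binary response coded 0/1; both classes must be present.
#' @param design As in [fit_linear()].
#' @return A list: `coefficients` tibble, `converged`, `n_used`, `deviance`.
#' @export
fit_logistic <- function(y, design) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- sprintf("x%d", seq_len(ncol(design)))
  }
  ok <- complete.cases(y, design)
  y <- y[ok]
  if (!all(y %in% c(0, 1))) abort("`y` must be coded 0/1")
  if (length(unique(y)) < 2L) abort("both outcome classes must be present")
  X <- cbind(`(Intercept)` = 1, design[ok, , drop = FALSE])
  if (qr(X)$rank < ncol(X)) abort("singular design: predictors are collinear")
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 25)))
  mu <- fit$fitted.values
  # perfect separation: the model classifies every case with certainty
  if (all(abs(y - mu) < 1e-6)) {
    abort("perfect separation detected: logistic coefficients diverge")
  }
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(info)), error = function(e) solve(info))
  se <- sqrt(pmax(diag(cov), 0))
  z <- fit$coefficients / se
  list(
    coefficients = tibble(term = colnames(X), estimate = unname(fit$coefficients),
                          se = unname(se), p = unname(p_normal2(z))),
    converged = isTRUE(fit$converged), n_used = nrow(X),
    deviance = fit$deviance)
}

# fast per-SNP linear scan on a complete genotype matrix via
# Frisch-Waugh residualization; identical estimates/SEs to the per-SNP
# multiple regression (df accounted for the projected-out covariates)
fast_linear_scan <- function(G, y, C = NULL) {
  n <- nrow(G)
  if (is.null(C)) {
    X0 <- matrix(1, n, 1)
  } else {
    X0 <- cbind(1, as.matrix(C))
  }
  q <- qr(X0)
  ry <- qr.resid(q, y)
  rG <- qr.resid(q, G)
  sxx <- colSums(rG^2)
  sxy <- colSums(rG * ry)
  beta <- sxy / sxx
  df <- n - ncol(X0) - 1L
  rss <- sum(ry^2) - beta^2 * sxx
  s2 <- pmax(rss, 0) / df
  se <- sqrt(s2 / sxx)
  tstat <- beta / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  tibble(beta = beta, se = se, p = p, n_used = n)
}

#' Per-SNP association scan
#'
#' Regresses a trait on each SNP's additive dosage plus covariates — linear
#' regression for a continuous trait, logistic for a binary one — using
#' complete cases per SNP (no global row deletion). Monomorphic SNPs are
#' flagged `not_testable` and excluded from instrument selection.
#'
#' @param g A genotype table.
#' @param pheno Phenotype tibble with an `individual_id` column aligned to
#'   `g` plus the trait and covariate columns.
#' @param trait Name of the trait column to scan.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param model `"linear"` or `"logistic"`; defaults to logistic when the
#'   trait takes only values 0/1.
#' @return A tibble of per-SNP summary statistics: `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`, `n_used`, `model`,
#'   `status`. Effect sizes are per copy of the effect allele (trait units
#'   for linear, log-odds for logistic).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 800, causal_effect = 0.3,
#'                                      seed = 3))
#' gwas(cohort$genotypes, cohort$phenotypes, trait = "exposure")
#' @export
gwas <- function(g, pheno, trait, covariates = character(), model = NULL) {
  stopifnot(inherits(g, "geno_tbl"))
  pheno <- as_tibble(pheno)
  if (!trait %in% names(pheno)) abort(sprintf("trait column `%s` not found", trait))
  missing_cov <- setdiff(covariates, names(pheno))
  if (length(missing_cov)) {
    abort(sprintf("covariate column(s) not found: %s", paste(missing_cov, collapse = ", ")))
  }
  pheno <- pheno[match(g$individual_id, pheno$individual_id), ]
  if (anyNA(pheno$individual_id)) abort("phenotype rows missing for some genotyped individuals")
  G <- geno_matrix(g)
  y <- pheno[[trait]]
  C <- if (length(covariates)) as.matrix(pheno[covariates]) else NULL
  if (is.null(model)) {
    model <- if (all(y[!is.na(y)] %in% c(0, 1))) "logistic" else "linear"
  }
  model <- match.arg(model, c("linear", "logistic"))
  info <- snp_info(g)

  base_ok <- !is.na(y) & (if (is.null(C)) TRUE else complete.cases(C))
  mono <- apply(G, 2, function(x) {
    v <- x[!is.na(x) & base_ok]
    length(v) < 3 || var(v) == 0
  })

  res <- tibble(snp_id = info$snp_id, chrom = info$chrom, pos = info$pos,
                effect_allele = info$effect_allele,
                other_allele = info$other_allele,
                beta = NA_real_, se = NA_real_, p = NA_real_,
                n_used = NA_integer_, model = model,
                status = unname(ifelse(mono, "not_testable", "ok")))

  test_idx <- which(!mono)
  if (!length(test_idx)) return(res)

  if (model == "linear" && !anyNA(G[base_ok, test_idx])) {
    sc <- fast_linear_scan(G[base_ok, test_idx, drop = FALSE], y[base_ok],
                           if (is.null(C)) NULL else C[base_ok, , drop = FALSE])
    res$beta[test_idx] <- sc$beta
    res$se[test_idx] <- sc$se
    res$p[test_idx] <- sc$p
    res$n_used[test_idx] <- sc$n_used
    return(res)
  }
  for (j in test_idx) {
    design <- cbind(dosage = G[, j], C)
    fit <- tryCatch({
      if (model == "linear") fit_linear(y, design) else fit_logistic(y, design)
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      res$status[j] <- conditionMessage(fit)
      next
    }
    co <- fit$coefficients[fit$coefficients$term == "dosage", ]
    res$beta[j] <- co$estimate
    res$se[j] <- co$se
    res$p[j] <- co$p
    res$n_used[j] <- fit$n_used
    if (model == "logistic" && !fit$converged) res$status[j] <- "not_converged"
  }
  res
}

#' Select candidate instruments by p-value
#'
#' Retains SNPs whose association p-value is strictly below the selection
#' threshold (default 5e-6, the conventional suggestive genome-wide level),
#' sorted by p ascending. An empty selection is legal and warned about, not
#' an error.
#'
#' @param results A [gwas()] summary-statistics tibble.
#' @param p_threshold Strict selection threshold.
#' @return The selected rows, ordered by p.
#' @export
select_instruments <- function(results, p_threshold = 5e-6) {
  results <- as_tibble(results)
  if (!nrow(results)) {
    warn("empty association results: no instruments to select")
    return(results)
  }
  out <- results |>
    dplyr::filter(.data$status == "ok", !is.na(.data$p), .data$p < p_threshold) |>
    dplyr::arrange(.data$p)
  if (!nrow(out)) warn(sprintf("no SNP passed p < %g", p_threshold))
  attr(out, "p_threshold") <- p_threshold
  out
}

#' Partial F-statistic of a single instrument
#'
#' Instrument-strength statistic: the partial F for adding one SNP to the
#' covariate-only linear model of the exposure,
#' \eqn{F = (RSS_0 - RSS_1) / (RSS_1 / (n - p_1))}, which equals the squared
#' t-statistic of the SNP coefficient in the full model.
#'
#' @param g_j Dosage vector of the SNP.
#' @param exposure Continuous exposure vector.
#' @param covariates Optional covariate matrix/data frame.
#' @return The F value (scalar).
#' @export
f_statistic <- function(g_j, exposure, covariates = NULL) {
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- complete.cases(exposure, g_j, if (is.null(C)) rep(TRUE, length(g_j)) else C)
  y <- exposure[ok]
  gv <- g_j[ok]
  Cok <- if (is.null(C)) NULL else C[ok, , drop = FALSE]
  full <- fit_linear(y, cbind(dosage = gv, Cok))
  rss1 <- full$rss
  rss0 <- if (is.null(Cok)) {
    sum((y - mean(y))^2)
  } else {
    fit_linear(y, Cok)$rss
  }
  (rss0 - rss1) / (rss1 / full$df_residual)
}

#' Screen candidate instruments for weak-instrument bias
#'
#' Computes the per-SNP partial F-statistic of each candidate against the
#' exposure (covariate-adjusted) and retains those with F greater than or
#' equal to the threshold (default 10, the conventional weak-instrument
#' rule). An empty surviving set halts the pipeline with a diagnostic,
#' because MR cannot proceed without instruments.
#'
#' @param candidates Output of [select_instruments()].
#' @param g Genotype table containing the candidate SNPs.
#' @param pheno Phenotype tibble.
#' @param exposure Name of the exposure column.
#' @param covariates Covariate column names.
#' @param f_threshold Inclusive retention threshold.
#' @return An `instrument_set` tibble: `snp_id`, `beta_exposure`,
#'   `se_exposure`, `p_exposure`, `f_statistic`, with the thresholds stored
#'   as attributes.
#' @export
screen_instruments <- function(candidates, g, pheno, exposure,
                               covariates = character(), f_threshold = 10) {
  candidates <- as_tibble(candidates)
  if (!nrow(candidates)) {
    abort("no candidate instruments survive screening: MR cannot proceed")
  }
  pheno <- as_tibble(pheno)[match(g$individual_id, pheno$individual_id), ]
  G <- geno_matrix(g)
  C <- if (length(covariates)) as.matrix(pheno[covariates]) else NULL
  fs <- vapply(candidates$snp_id, function(s) {
    if (!s %in% colnames(G)) abort(sprintf("candidate SNP `%s` absent from genotype table", s))
    f_statistic(G[, s], pheno[[exposure]], C)
  }, numeric(1))
  out <- tibble(snp_id = candidates$snp_id,
                beta_exposure = candidates$beta,
                se_exposure = candidates$se,
                p_exposure = candidates$p,
                f_statistic = unname(fs)) |>
    dplyr::filter(.data$f_statistic >= f_threshold)
  if (!nrow(out)) {
    abort(sprintf("all candidates have F < %g: MR cannot proceed (weak instruments)",
                  f_threshold))
  }
  structure(out, f_threshold = f_threshold,
            p_threshold = attr(candidates, "p_threshold"),
            class = c("instrument_set", class(out)))
}
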