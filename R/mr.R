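#' Harmonize instrument and outcome summary statistics
#'
#' Joins the exposure-side instrument set with outcome association results on
#' shared SNPs, checks allele annotation agrees, and orients every
#' instrument so its exposure effect is non-negative (flipping the outcome
#' effect in tandem, which leaves every ratio estimate unchanged).
#'
#' @param instruments An `instrument_set` from [screen_instruments()], or any
#'   tibble with `snp_id`, `beta_exposure`, `se_exposure` (and optionally
#'   `effect_allele`).
#' @param outcome_stats A [gwas()] tibble for the outcome over (at least) the
#'   instrument SNPs.
#' @return A `harmonized_instruments` tibble: `snp_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `flipped`.
#' @export
harmonize <- function(instruments, outcome_stats) {
  instruments <- as_tibble(instruments)
  outcome_stats <- as_tibble(outcome_stats)
  missing <- setdiff(instruments$snp_id, outcome_stats$snp_id)
  if (length(missing)) {
    abort(sprintf("outcome statistics missing for instrument(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- outcome_stats[match(instruments$snp_id, outcome_stats$snp_id), ]
  if ("effect_allele" %in% names(instruments) &&
      "effect_allele" %in% names(out)) {
    bad <- instruments$snp_id[instruments$effect_allele != out$effect_allele]
    if (length(bad)) {
      abort(sprintf("effect-allele mismatch for instrument(s): %s",
                    paste(bad, collapse = ", ")))
    }
  }
  if (any(out$status != "ok")) {
    abort(sprintf("outcome statistics not testable for instrument(s): %s",
                  paste(out$snp_id[out$status != "ok"], collapse = ", ")))
  }
  h <- tibble(snp_id = instruments$snp_id,
              beta_exposure = instruments$beta_exposure,
              se_exposure = instruments$se_exposure,
              beta_outcome = out$beta,
              se_outcome = out$se)
  if (any(h$beta_exposure == 0)) abort("zero exposure effect cannot be oriented")
  flip <- h$beta_exposure < 0
  h$beta_exposure[flip] <- -h$beta_exposure[flip]
  h$beta_outcome[flip] <- -h$beta_outcome[flip]
  h$flipped <- flip
  structure(h, class = c("harmonized_instruments", class(h)))
}

check_harmonized <- function(h, min_instruments = 1L, method = "this estimator") {
  h <- as_tibble(h)
  need <- c("snp_id", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(h))
  if (length(miss)) {
    abort(paste("harmonized instruments need columns:", paste(miss, collapse = ", ")))
  }
  if (nrow(h) < min_instruments) {
    abort(sprintf("%s needs at least %d instruments, got %d",
                  method, min_instruments, nrow(h)))
  }
  if (any(h$se_exposure <= 0) || any(h$se_outcome <= 0)) {
    abort("standard errors must be positive")
  }
  if (any(h$beta_exposure == 0)) abort("zero exposure effects are not allowed")
  h
}

#' Per-instrument ratio (Wald) estimates
#'
#' The single-instrument causal estimate
#' \eqn{\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}} with first-order
#' delta-method standard error \eqn{se(\hat\beta_{Yj}) / |\hat\beta_{Xj}|}.
#'
#' @param h Harmonized instruments (see [harmonize()]).
#' @return A tibble: `snp_id`, `ratio`, `se_ratio`.
#' @export
ratio_estimates <- function(h) {
  h <- check_harmonized(h, 1L, "ratio_estimates")
  tibble(snp_id = h$snp_id,
         ratio = h$beta_outcome / h$beta_exposure,
         se_ratio = h$se_outcome / abs(h$beta_exposure))
}

new_mr_result <- function(method, estimate, se, p = NULL, n_instruments,
                          extra = NULL) {
  ci <- estimate + c(-1, 1) * Z95 * se
  out <- tibble(method = method, estimate = estimate, se = se,
                ci_lower = ci[1], ci_upper = ci[2],
                p = p %||% p_normal2(estimate / se),
                n_instruments = n_instruments)
  if (!is.null(extra)) out <- dplyr::bind_cols(out, as_tibble(extra))
  structure(out, class = c("mr_result", class(out)))
}

#' Inverse-variance-weighted causal estimate
#'
#' The IVW meta-analysis of the per-instrument ratio estimates,
#' \deqn{\hat\theta_{IVW} = \frac{\sum_j \hat\beta_{Yj}\hat\beta_{Xj}/se(\hat\beta_{Yj})^2}
#'   {\sum_j \hat\beta_{Xj}^2/se(\hat\beta_{Yj})^2},}
#' equivalently weighted least squares of the outcome effects on the
#' exposure effects through the origin with weights
#' \eqn{se(\hat\beta_{Yj})^{-2}}. The fixed-effect standard error is
#' \eqn{(\sum_j \hat\beta_{Xj}^2/se(\hat\beta_{Yj})^2)^{-1/2}}; the
#' multiplicative random-effects model inflates it by
#' \eqn{\max(1, \hat\sigma)} where \eqn{\hat\sigma^2} is the weighted
#' residual mean square of the through-origin regression. Valid when the
#' instruments are mutually uncorrelated and pleiotropy-free; asymptotically
#' equivalent to two-stage least squares on the individual-level data.
#'
#' @param h Harmonized instruments.
#' @param model `"fixed"` (default) or `"multiplicative_random"`. A single
#'   instrument forces the fixed model (with a warning if random-effects was
#'   requested).
#' @return A one-row `mr_result` tibble: `method`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `p` (two-sided normal), `n_instruments`.
#' @examples
#' h <- tibble::tibble(snp_id = c("a", "b"), beta_exposure = c(1, 1),
#'                     se_exposure = c(0.1, 0.1), beta_outcome = c(0.2, 0.4),
#'                     se_outcome = c(0.05, 0.05))
#' mr_ivw(h)
#' @export
mr_ivw <- function(h, model = c("fixed", "multiplicative_random")) {
  model <- match.arg(model)
  h <- check_harmonized(h, 1L, "IVW")
  w <- 1 / h$se_outcome^2
  sxx <- sum(w * h$beta_exposure^2)
  est <- sum(w * h$beta_outcome * h$beta_exposure) / sxx
  se <- sqrt(1 / sxx)
  if (model == "multiplicative_random") {
    if (nrow(h) < 2L) {
      warn("single instrument: falling back to the fixed-effect model")
    } else {
      sigma2 <- sum(w * (h$beta_outcome - est * h$beta_exposure)^2) / (nrow(h) - 1L)
      se <- se * max(1, sqrt(sigma2))
    }
  }
  new_mr_result("IVW", est, se, n_instruments = nrow(h),
                extra = tibble(model = model))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the
#' orientation-harmonized exposure effects with a free intercept and weights
#' \eqn{se(\hat\beta_{Yj})^{-2}}. The slope estimates the causal effect
#' under the InSIDE assumption (pleiotropic effects independent of
#' instrument strength); the intercept estimates average directional
#' pleiotropy, and its test is the standard check that the IVW estimate is
#' not biased by directional pleiotropy. Standard errors carry a residual
#' variance factor floored at 1 (never shrunk below the fixed-effect
#' precision).
#'
#' @param h Harmonized instruments (at least 3: slope, intercept, residual
#'   degrees of freedom).
#' @return A one-row `mr_result` with additional columns `intercept`,
#'   `intercept_se`, `intercept_ci_lower`, `intercept_ci_upper`,
#'   `intercept_p`.
#' @export
mr_egger <- function(h) {
  h <- check_harmonized(h, 3L, "MR-Egger")
  w <- 1 / h$se_outcome^2
  x <- h$beta_exposure
  y <- h$beta_outcome
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx == 0) abort("MR-Egger undefined: all exposure effects identical")
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  rss_w <- sum(w * (y - intercept - slope * x)^2)
  sigma2 <- max(1, rss_w / (nrow(h) - 2L))
  se_slope <- sqrt(sigma2 / sxx)
  se_int <- sqrt(sigma2 * (1 / sw + xbar^2 / sxx))
  int_ci <- intercept + c(-1, 1) * Z95 * se_int
  new_mr_result("MR-Egger", slope, se_slope, n_instruments = nrow(h),
                extra = tibble(intercept = intercept, intercept_se = se_int,
                               intercept_ci_lower = int_ci[1],
                               intercept_ci_upper = int_ci[2],
                               intercept_p = p_normal2(intercept / se_int)))
}

# weighted median of ratio estimates by percentile interpolation:
# order ratios, cumulative standardized weights p_j = (S_j - w_j/2)/S_total,
# linearly interpolate the ratio at cumulative weight 0.5
weighted_median_est <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  approx(cw, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

mr_median_impl <- function(h, weighted, n_boot, seed) {
  label <- if (weighted) "Weighted median" else "Simple median"
  h <- check_harmonized(h, 3L, label)
  J <- nrow(h)
  point <- function(bx, by) {
    r <- by / bx
    w <- if (weighted) bx^2 / h$se_outcome^2 else rep(1, J)
    weighted_median_est(r, w)
  }
  est <- point(h$beta_exposure, h$beta_outcome)
  boots <- withr::with_seed(derive_seed(seed, paste0("median_boot_", label)), {
    bx <- matrix(rnorm(J * n_boot, h$beta_exposure, h$se_exposure), J, n_boot)
    by <- matrix(rnorm(J * n_boot, h$beta_outcome, h$se_outcome), J, n_boot)
    vapply(seq_len(n_boot), function(b) point(bx[, b], by[, b]), numeric(1))
  })
  se <- sd(boots)
  new_mr_result(label, est, se, n_instruments = J)
}

#' Median-based causal estimators
#'
#' `mr_simple_median()` takes the (interpolated) median of the
#' per-instrument ratio estimates with equal weights; it is consistent when
#' at least half of the instruments are valid. `mr_weighted_median()` weights
#' each ratio by its inverse delta-method variance
#' (\eqn{\hat\beta_{Xj}^2 / se(\hat\beta_{Yj})^2}) and interpolates the ratio
#' at cumulative standardized weight 0.5; it is consistent when valid
#' instruments carry more than half of the total weight. Standard errors
#' come from a seeded parametric bootstrap (instrument-wise normal
#' resampling of both effect estimates), and p-values from the normal
#' approximation with the bootstrap SE.
#'
#' @param h Harmonized instruments (at least 3).
#' @param n_boot Bootstrap draws (default 2000).
#' @param seed Integer seed making the bootstrap reproducible.
#' @return A one-row `mr_result` tibble.
#' @export
mr_simple_median <- function(h, n_boot = 2000, seed = 1L) {
  mr_median_impl(h, weighted = FALSE, n_boot = n_boot, seed = seed)
}

#' @rdname mr_simple_median
#' @export
mr_weighted_median <- function(h, n_boot = 2000, seed = 1L) {
  mr_median_impl(h, weighted = TRUE, n_boot = n_boot, seed = seed)
}

#' Convert a log-odds causal estimate to an odds ratio
#'
#' Exponentiates the estimate and confidence limits of an `mr_result`
#' obtained with a binary outcome (log-odds scale).
#'
#' @param r An `mr_result` tibble (any number of rows).
#' @return A tibble: `method`, `or`, `or_ci_lower`, `or_ci_upper`, `p`.
#' @export
to_odds_ratio <- function(r) {
  r <- as_tibble(r)
  need <- c("method", "estimate", "ci_lower", "ci_upper", "p")
  if (!all(need %in% names(r))) abort("`r` must be an mr_result tibble")
  tibble(method = r$method, or = exp(r$estimate),
         or_ci_lower = exp(r$ci_lower), or_ci_upper = exp(r$ci_upper),
         p = r$p)
}

#' Run the four MR estimators on one harmonized instrument set
#'
#' IVW, simple median, weighted median and MR-Egger (whose intercept is
#' reported as its own row, the conventional table layout). Estimators that
#' fail (e.g. too few instruments) yield a row with `status` explaining why,
#' without aborting the others.
#'
#' @param h Harmonized instruments.
#' @param seed Seed for the median bootstrap streams.
#' @param methods Subset of `c("ivw", "simple_median", "weighted_median",
#'   "egger")`.
#' @param n_boot Bootstrap draws for the medians.
#' @param ivw_model Passed to [mr_ivw()].
#' @return An `mr_result` tibble, one row per method (plus `(Intercept)`
#'   after the MR-Egger row), columns `method`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `p`, `n_instruments`, `status`.
#' @export
mr_all <- function(h, seed = 1L,
                   methods = c("ivw", "simple_median", "weighted_median", "egger"),
                   n_boot = 2000, ivw_model = "fixed") {
  methods <- match.arg(methods, several.ok = TRUE)
  runs <- list(
    ivw = function() mr_ivw(h, model = ivw_model),
    simple_median = function() mr_simple_median(h, n_boot = n_boot, seed = seed),
    weighted_median = function() mr_weighted_median(h, n_boot = n_boot, seed = seed),
    egger = function() {
      e <- mr_egger(h)
      dplyr::bind_rows(
        dplyr::select(e, "method", "estimate", "se", "ci_lower", "ci_upper",
                      "p", "n_instruments"),
        tibble(method = "(Intercept)", estimate = e$intercept,
               se = e$intercept_se, ci_lower = e$intercept_ci_lower,
               ci_upper = e$intercept_ci_upper, p = e$intercept_p,
               n_instruments = e$n_instruments))
    })
  rows <- purrr::map(methods, function(m) {
    res <- tryCatch(runs[[m]](), error = function(e) e)
    if (inherits(res, "error")) {
      tibble(method = m, estimate = NA_real_, se = NA_real_,
             ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
             n_instruments = nrow(as_tibble(h)),
             status = conditionMessage(res))
    } else {
      res$status <- "ok"
      dplyr::select(as_tibble(res), "method", "estimate", "se", "ci_lower",
                    "ci_upper", "p", "n_instruments", "status")
    }
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("mr_result", class(out)))
}
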