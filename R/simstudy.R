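#' Two-stage least squares on individual-level data
#'
#' The classical instrumental-variable estimator for a continuous outcome:
#' regress the exposure on all instruments jointly (first stage), then the
#' outcome on the fitted exposure (second stage), with the usual 2SLS
#' standard error using second-stage residuals computed at the observed
#' exposure. IVW on one-sample summary statistics tends to this estimate
#' asymptotically when the instruments are uncorrelated.
#'
#' @param exposure,outcome Numeric vectors.
#' @param G Instrument dosage matrix (individuals x instruments).
#' @param covariates Optional covariate matrix included in both stages.
#' @return A tibble: `estimate`, `se`, `p`.
#' @export
tsls <- function(exposure, outcome, G, covariates = NULL) {
  G <- as.matrix(G)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- complete.cases(exposure, outcome, G, if (is.null(C)) rep(TRUE, length(exposure)) else C)
  x <- exposure[ok]; y <- outcome[ok]
  Z <- cbind(1, G[ok, , drop = FALSE], C)
  xhat <- qr.fitted(qr(Z), x)
  X2 <- cbind(1, xhat = xhat, if (is.null(C)) NULL else C[ok, , drop = FALSE])
  q2 <- qr(X2)
  beta <- qr.coef(q2, y)
  # 2SLS residuals use the observed exposure, not the fitted one
  X2_obs <- X2; X2_obs[, "xhat"] <- x
  resid <- y - drop(X2_obs %*% beta)
  s2 <- sum(resid^2) / (length(y) - ncol(X2))
  R2 <- qr.R(q2)
  cov_un <- chol2inv(R2)
  dvar <- numeric(ncol(X2)); dvar[q2$pivot] <- diag(cov_un)
  se <- sqrt(s2 * dvar[2])
  est <- unname(beta["xhat"])
  tibble(estimate = est, se = se, p = p_normal2(est / se))
}

# minimal per-block association scan used by the scenario runner
scan_block <- function(G, y, model, covariates = NULL) {
  if (model == "linear") {
    sc <- fast_linear_scan(G, y, covariates)
    return(tibble(snp_id = colnames(G), beta = sc$beta, se = sc$se,
                  p = sc$p, n_used = sc$n_used, status = "ok"))
  }
  rows <- purrr::map(seq_len(ncol(G)), function(j) {
    fit <- fit_logistic(y, cbind(dosage = G[, j], covariates))
    co <- fit$coefficients[fit$coefficients$term == "dosage", ]
    tibble(snp_id = colnames(G)[j], beta = co$estimate, se = co$se,
           p = co$p, n_used = fit$n_used,
           status = if (fit$converged) "ok" else "not_converged")
  })
  dplyr::bind_rows(rows)
}

harmonize_blocks <- function(exp_stats, out_stats) {
  harmonize(
    tibble(snp_id = exp_stats$snp_id, beta_exposure = exp_stats$beta,
           se_exposure = exp_stats$se),
    dplyr::mutate(out_stats, effect_allele = "A"))
}

#' Registered simulation scenarios
#'
#' Returns the labels of the registered estimator-validation scenarios used
#' by [simulation_study()]:
#'
#' * `valid_ivs` — five valid, independent instruments of a continuous
#'   exposure; continuous outcome; causal effect `theta` (default 0.2) —
#'   parameter recovery, coverage and (with `theta = 0`) type-I error.
#' * `balanced_pleiotropy` — ten instruments with zero-mean pleiotropic
#'   effects (InSIDE holds).
#' * `directional_pleiotropy_inside` — pleiotropic effects with nonzero mean
#'   `alpha_mean` (default 0.08, sd 0.02) drawn independently of instrument
#'   strength; `invalid_frac < 1` instead gives that fraction of randomly
#'   chosen instruments a fixed offset `alpha_mean`, the minority-invalid
#'   setting where the weighted median is consistent.
#' * `weak_instruments` — five instruments with per-SNP F far below 10.
#' * `reverse_causation` — data generated with the binary trait causing the
#'   continuous one; the forward analysis is run and should find nothing.
#' * `winner_curse_split_compare` — instruments selected by p-value in the
#'   estimation sample (one-sample design) versus in an independent half
#'   (split-sample), quantifying winner's-curse bias.
#'
#' @return Character vector of scenario labels.
#' @export
mr_scenarios <- function() {
  c("valid_ivs", "balanced_pleiotropy", "directional_pleiotropy_inside",
    "weak_instruments", "reverse_causation", "winner_curse_split_compare")
}

scenario_params <- function(scenario, overrides) {
  defaults <- switch(scenario,
    valid_ivs = list(n = 10000, theta = 0.2,
                     beta_x = c(0.20, 0.15, 0.25, 0.18, 0.22),
                     maf = c(0.2, 0.25, 0.3, 0.35, 0.4)),
    balanced_pleiotropy = list(n = 10000, theta = 0.2,
                               beta_x = seq(0.1, 0.35, length.out = 10),
                               maf = seq(0.15, 0.45, length.out = 10),
                               alpha_sd = 0.05),
    directional_pleiotropy_inside = list(n = 10000, theta = 0.2,
                                         beta_x = seq(0.1, 0.35, length.out = 10),
                                         maf = seq(0.15, 0.45, length.out = 10),
                                         alpha_mean = 0.08, alpha_sd = 0.02,
                                         invalid_frac = 1),
    weak_instruments = list(n = 5000, theta = 0.2, beta_x = rep(0.03, 5),
                            maf = rep(0.3, 5)),
    reverse_causation = list(n = 5000, theta_rev = 0.8,
                             beta_x = c(0.20, 0.15, 0.25, 0.18, 0.22),
                             maf = c(0.2, 0.25, 0.3, 0.35, 0.4),
                             beta_y = rep(0.25, 5), maf_y = rep(0.3, 5)),
    winner_curse_split_compare = list(n = 6000, theta = 0.2,
                                      beta_x = rep(0.085, 20),
                                      maf = rep(0.25, 20),
                                      p_select = 1e-3, conf_beta = 0.5),
    abort(sprintf("unknown scenario `%s`; registered scenarios: %s",
                  scenario, paste(mr_scenarios(), collapse = ", "))))
  utils::modifyList(defaults, overrides)
}

run_scenario_rep <- function(scenario, pars, methods, n_boot, rep_seed) {
  if (scenario == "winner_curse_split_compare") {
    return(winner_curse_rep(pars, rep_seed))
  }
  if (scenario == "reverse_causation") {
    cfg <- sim_config(n_individuals = pars$n,
                      instrument_effects = pars$beta_x,
                      outcome_instrument_effects = pars$beta_y,
                      maf = c(pars$maf, pars$maf_y),
                      reverse_effect = pars$theta_rev,
                      direction = "reverse", seed = rep_seed)
    cohort <- simulate_cohort(cfg)
    G <- geno_matrix(cohort$genotypes)
    Gx <- G[, seq_along(pars$beta_x), drop = FALSE]
    x <- cohort$phenotypes$exposure
    y <- cohort$phenotypes$outcome
    h <- harmonize_blocks(scan_block(Gx, x, "linear"),
                          scan_block(Gx, y, "logistic"))
    res <- mr_all(h, seed = rep_seed, methods = methods, n_boot = n_boot)
    return(dplyr::mutate(as_tibble(res), truth = 0))
  }
  alpha <- NULL
  truth_int <- 0
  if (scenario %in% c("balanced_pleiotropy", "directional_pleiotropy_inside")) {
    J <- length(pars$beta_x)
    alpha <- withr::with_seed(derive_seed(rep_seed, "scenario_alpha"), {
      if (scenario == "balanced_pleiotropy") {
        rnorm(J, 0, pars$alpha_sd)
      } else if (pars$invalid_frac < 1) {
        # a random minority of instruments gets a fixed directional offset
        pars$alpha_mean * (sample.int(J) <= ceiling(pars$invalid_frac * J))
      } else {
        rnorm(J, pars$alpha_mean, pars$alpha_sd)
      }
    })
    truth_int <- if (scenario == "balanced_pleiotropy") 0 else mean(alpha)
  }
  cfg <- sim_config(n_individuals = pars$n, instrument_effects = pars$beta_x,
                    maf = pars$maf, causal_effect = pars$theta,
                    pleiotropy = alpha %||% list(type = "none"),
                    outcome_kind = "continuous", seed = rep_seed)
  cohort <- simulate_cohort(cfg)
  G <- geno_matrix(cohort$genotypes)
  x <- cohort$phenotypes$exposure
  y <- cohort$phenotypes$outcome
  h <- harmonize_blocks(scan_block(G, x, "linear"), scan_block(G, y, "linear"))
  res <- mr_all(h, seed = rep_seed, methods = methods, n_boot = n_boot)
  out <- dplyr::mutate(as_tibble(res), truth = pars$theta)
  # report the Egger intercept against the generative mean pleiotropy
  if ("(Intercept)" %in% out$method) {
    out$method[out$method == "(Intercept)"] <- "egger_intercept"
    out$truth[out$method == "egger_intercept"] <- truth_int
  }
  out
}

winner_curse_rep <- function(pars, rep_seed) {
  # an unobserved confounder correlates the exposure- and outcome-scan errors;
  # selecting instruments on the estimation sample then drags the IVW estimate
  # toward the confounded observational association (winner's curse), while
  # split-sample selection leaves the estimate unbiased
  conf <- tibble(name = "u", dist = "normal", mean = 0, sd = 1,
                 beta_exposure = pars$conf_beta, beta_outcome = pars$conf_beta)
  cfg <- sim_config(n_individuals = pars$n, instrument_effects = pars$beta_x,
                    maf = pars$maf, causal_effect = pars$theta,
                    confounders = conf,
                    outcome_kind = "continuous", seed = rep_seed)
  cohort <- simulate_cohort(cfg)
  G <- geno_matrix(cohort$genotypes)
  x <- cohort$phenotypes$exposure
  y <- cohort$phenotypes$outcome
  n <- nrow(G)
  ivw_on <- function(idx_sel, idx_est) {
    ex <- scan_block(G[idx_est, idx_sel, drop = FALSE], x[idx_est], "linear")
    ot <- scan_block(G[idx_est, idx_sel, drop = FALSE], y[idx_est], "linear")
    mr_ivw(harmonize_blocks(ex, ot))
  }
  # one-sample design: select and estimate in the full cohort
  full <- scan_block(G, x, "linear")
  sel_full <- which(full$p < pars$p_select)
  row_in <- if (length(sel_full)) {
    dplyr::mutate(as_tibble(ivw_on(sel_full, seq_len(n))),
                  method = "ivw_insample", status = "ok")
  }
  # split-sample: select in half A, estimate in half B
  half <- withr::with_seed(derive_seed(rep_seed, "winner_split"),
                           sample.int(n, floor(n / 2)))
  a_stats <- scan_block(G[half, , drop = FALSE], x[half], "linear")
  sel_a <- which(a_stats$p < pars$p_select)
  row_sp <- if (length(sel_a)) {
    dplyr::mutate(as_tibble(ivw_on(sel_a, setdiff(seq_len(n), half))),
                  method = "ivw_split", status = "ok")
  }
  out <- dplyr::bind_rows(row_in, row_sp)
  if (!nrow(out)) return(NULL)
  dplyr::mutate(out, truth = pars$theta)
}

#' Monte-Carlo study of the MR estimators
#'
#' Replicates registered generative scenarios (see [mr_scenarios()]) and
#' summarizes each estimator's behaviour: mean estimate and bias against the
#' generative truth, empirical standard error, mean model-based standard
#' error, 95% confidence-interval coverage, and rejection rate of the
#' two-sided test at 0.05. Replicate-level results are kept in the
#' `replicates` attribute for audit.
#'
#' @param scenarios Character vector of registered scenario labels.
#' @param n_replicates Replicates per scenario.
#' @param seed Root seed; replicate seeds are derived deterministically.
#' @param overrides Named list (per call, applied to every scenario) of
#'   scenario parameter overrides, e.g. `list(theta = 0)` for a null run.
#' @param methods Estimators to run (default IVW, weighted median, Egger).
#' @param n_boot Bootstrap draws for median standard errors; point estimates
#'   do not depend on it (default 200 keeps large studies fast).
#' @return A `scenario_metrics` tibble: one row per scenario x method.
#' @examples
#' \donttest{
#' simulation_study("valid_ivs", n_replicates = 20, seed = 1,
#'                  overrides = list(n = 2000))
#' }
#' @export
simulation_study <- function(scenarios, n_replicates = 200, seed = 1L,
                             overrides = list(),
                             methods = c("ivw", "weighted_median", "egger"),
                             n_boot = 200) {
  n_replicates <- check_positive_count(n_replicates, "n_replicates")
  all_reps <- purrr::map(scenarios, function(sc) {
    pars <- scenario_params(sc, overrides)
    reps <- purrr::map(seq_len(n_replicates), function(i) {
      rs <- derive_seed(seed, sprintf("%s_rep%06d", sc, i))
      r <- run_scenario_rep(sc, pars, methods, n_boot, rs)
      if (is.null(r)) return(NULL)
      dplyr::mutate(r, scenario = sc, replicate = i, .before = 1)
    })
    dplyr::bind_rows(reps)
  })
  reps <- dplyr::bind_rows(all_reps)
  metrics <- reps |>
    dplyr::filter(.data$status == "ok", !is.na(.data$estimate)) |>
    dplyr::group_by(.data$scenario, .data$method) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_estimate = mean(.data$estimate),
      mean_bias = mean(.data$estimate - .data$truth),
      empirical_se = sd(.data$estimate),
      mean_model_se = mean(.data$se),
      coverage = mean(.data$ci_lower <= .data$truth & .data$truth <= .data$ci_upper),
      rejection_rate = mean(.data$p < 0.05),
      # generative truth last: earlier summaries must see the per-replicate
      # truth column, not this scalar
      truth = .data$truth[1],
      .groups = "drop")
  structure(metrics, replicates = reps,
            class = c("scenario_metrics", class(metrics)))
}

#' @export
tidy.scenario_metrics <- function(x, ...) as_tibble(x)

#' @rdname simulation_study
#' @param x A `scenario_metrics` table.
#' @export
scenario_replicates <- function(x) attr(x, "replicates")
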