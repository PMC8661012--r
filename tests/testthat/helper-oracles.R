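# Independent oracles used across the suite. Each is deliberately coded from
# first principles (closed forms, full enumeration, explicit normal
# equations), sharing no code path with the implementation it checks.

# exact HWE p-value by brute-force enumeration of the conditional
# heterozygote distribution with lgamma arithmetic
hwe_enum_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  nA <- 2 * aa + ab
  nB <- 2 * bb + ab
  rare <- min(nA, nB)
  if (rare == 0) return(1)
  hs <- seq.int(rare %% 2, rare, by = 2L)
  logp <- vapply(hs, function(h) {
    naa <- (nA - h) / 2
    nbb <- (nB - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(ab, hs)]
  min(sum(p[p <= obs * (1 + 1e-12)]), 1)
}

# weighted least squares through the origin via explicit normal equations
wls_origin_oracle <- function(x, y, w) {
  est <- sum(w * x * y) / sum(w * x^2)
  list(estimate = est, se = sqrt(1 / sum(w * x^2)))
}

# weighted regression with intercept via explicit 2x2 normal equations
wls_line_oracle <- function(x, y, w, floor_sigma2 = TRUE) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  beta <- solve(A, b)
  res <- y - X %*% beta
  s2 <- sum(w * res^2) / (length(y) - 2)
  if (floor_sigma2) s2 <- max(1, s2)
  cov <- s2 * solve(A)
  list(intercept = beta[1], slope = beta[2],
       se_intercept = sqrt(cov[1, 1]), se_slope = sqrt(cov[2, 2]))
}

# OLS by explicit (X'X)^{-1} X'y arithmetic
ols_oracle <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(XtX_inv) * s2)
  list(beta = drop(beta), se = se,
       p = 2 * pt(abs(drop(beta) / se), df, lower.tail = FALSE))
}

# logistic MLE by an independently coded Newton-Raphson on the score
newton_logistic_oracle <- function(y, X, tol = 1e-12, maxit = 100) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * (mu * (1 - mu)))
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  info <- t(X) %*% (X * (mu * (1 - mu)))
  list(beta = beta, se = sqrt(diag(solve(info))))
}

# random harmonized instrument sets for estimator fixtures
random_harmonized <- function(J, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      snp_id = sprintf("rs%03d", seq_len(J)),
      beta_exposure = runif(J, 0.05, 0.5),
      se_exposure = runif(J, 0.01, 0.05),
      beta_outcome = rnorm(J, 0.1, 0.2),
      se_outcome = runif(J, 0.02, 0.1))
  })
}

# standard small cohort used by several pipeline tests
valid_iv_cohort <- function(n = 4000, theta = 0.2, seed = 1,
                            outcome_kind = "continuous") {
  cfg <- sim_config(n_individuals = n,
                    instrument_effects = c(0.20, 0.15, 0.25, 0.18, 0.22),
                    maf = c(0.2, 0.25, 0.3, 0.35, 0.4),
                    causal_effect = theta, outcome_kind = outcome_kind,
                    seed = seed)
  simulate_cohort(cfg)
}
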