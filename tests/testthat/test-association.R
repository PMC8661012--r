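test_that("fit_linear matches the explicit normal-equation oracle", {
  withr::with_seed(51, {
    for (k in 1:5) {
      X <- matrix(rnorm(200 * 4), 200, 4)
      y <- drop(X %*% c(1, -0.5, 0, 2)) + rnorm(200)
      fit <- fit_linear(y, X)
      ref <- ols_oracle(y, X)
      expect_equal(fit$coefficients$estimate, unname(ref$beta), tolerance = 1e-10)
      expect_equal(fit$coefficients$se, unname(ref$se), tolerance = 1e-10)
      expect_equal(fit$coefficients$p, unname(ref$p), tolerance = 1e-10)
    }
  })
})

test_that("fit_linear handles exact and orthogonal designs", {
  x <- seq_len(50)
  fit <- fit_linear(3 + 2 * x, cbind(x = x))
  expect_equal(fit$coefficients$estimate, c(3, 2), tolerance = 1e-12)
  expect_lt(max(fit$coefficients$se), 1e-10)

  # orthogonal predictor: coefficient exactly zero
  x1 <- rep(c(-1, 1), 25)
  y <- rep(c(2, 2), 25) + rep(c(-1, 1), each = 25) * 0  # constant
  fit0 <- fit_linear(y + rnorm(50, 0, 0) , cbind(x = x1))
  expect_equal(fit0$coefficients$estimate[2], 0, tolerance = 1e-12)

  expect_error(fit_linear(rnorm(10), cbind(a = 1:10, b = 2 * (1:10))), "singular")
})

test_that("fit_logistic matches an independent Newton-Raphson oracle", {
  withr::with_seed(52, {
    for (k in 1:5) {
      X <- matrix(rnorm(500 * 3), 500, 3)
      y <- rbinom(500, 1, plogis(drop(X %*% c(0.5, -1, 0.3)) - 0.2))
      fit <- fit_logistic(y, X)
      ref <- newton_logistic_oracle(y, X)
      expect_equal(fit$coefficients$estimate, unname(ref$beta), tolerance = 1e-8)
      expect_equal(fit$coefficients$se, unname(ref$se), tolerance = 1e-6)
      expect_true(fit$converged)
    }
  })
})

test_that("fit_logistic closed forms, null behaviour and separation guard", {
  # intercept-only: log(k/(n-k)) exactly
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_logistic(y, matrix(numeric(0), 100, 0))
  expect_equal(fit$coefficients$estimate[1], log(30 / 70), tolerance = 1e-10)

  withr::with_seed(53, {
    yb <- rbinom(2000, 1, 0.5)
    x <- rnorm(2000)
    f <- fit_logistic(yb, cbind(x = x))
    expect_lt(abs(f$coefficients$estimate[2]), 3 * f$coefficients$se[2])
  })

  # perfectly separated data must error, not silently return
  xs <- c(rep(-1, 20), rep(1, 20))
  ys <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic(ys, cbind(x = xs)), "separation")
  expect_error(fit_logistic(rep(1, 50), cbind(x = rnorm(50))), "both outcome classes")
})

test_that("gwas recovers planted effects and flags monomorphic SNPs", {
  co <- valid_iv_cohort(n = 10000, theta = 0, seed = 55)
  g <- co$genotypes
  m <- geno_matrix(g)
  m[, 3] <- 0  # monomorphic
  g2 <- as_geno_tbl(m, snp_info(g))
  res <- gwas(g2, co$phenotypes, "exposure", model = "linear")
  expect_identical(res$status[3], "not_testable")
  expect_true(all(is.na(res$beta[3])))
  truth <- c(0.20, 0.15, NA, 0.18, 0.22)
  for (j in c(1, 2, 4, 5)) {
    expect_lt(abs(res$beta[j] - truth[j]), 3 * res$se[j])
  }
})

test_that("the fast linear scan equals per-SNP multiple regression", {
  co <- valid_iv_cohort(n = 500, theta = 0.2, seed = 56)
  ph <- co$phenotypes
  conf <- withr::with_seed(57, tibble::tibble(c1 = rnorm(500), c2 = rnorm(500)))
  ph <- dplyr::bind_cols(ph, conf)
  res <- gwas(co$genotypes, ph, "exposure", covariates = c("c1", "c2"),
              model = "linear")
  G <- geno_matrix(co$genotypes)
  for (j in 1:5) {
    ref <- ols_oracle(ph$exposure, cbind(G[, j], conf$c1, conf$c2))
    expect_equal(res$beta[j], unname(ref$beta[2]), tolerance = 1e-10)
    expect_equal(res$se[j], unname(ref$se[2]), tolerance = 1e-10)
  }
})

test_that("null gwas p-values are calibrated and uniform", {
  g <- simulate_genotypes(2000, runif(500, 0.1, 0.5), seed = 58)
  ph <- tibble::tibble(individual_id = g$individual_id,
                       y = withr::with_seed(59, rnorm(2000)))
  res <- gwas(g, ph, "y", model = "linear")
  rej <- mean(res$p < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))$statistic
  expect_lt(unname(ks), 1.949 / sqrt(500))  # 0.001-level critical value
})

test_that("instrument selection applies a strict threshold and sorts by p", {
  res <- tibble::tibble(snp_id = c("a", "b", "c"),
                        beta = 1, se = 1, p = c(1e-7, 5e-6, 1e-3),
                        status = "ok")
  sel <- select_instruments(res, p_threshold = 5e-6)
  expect_identical(sel$snp_id, "a")  # boundary 5e-6 excluded
  expect_warning(sel0 <- select_instruments(res, p_threshold = 1e-9), "no SNP")
  expect_identical(nrow(sel0), 0L)
  expect_warning(select_instruments(res[0, ]), "empty")
})

test_that("planted instruments are selected with near-certain power", {
  # 5 instruments sized for power > 0.99 at p < 5e-6, n = 15,000
  hits <- vapply(1:10, function(s) {
    co <- valid_iv_cohort(n = 15000, theta = 0, seed = 600 + s)
    res <- gwas(co$genotypes, co$phenotypes, "exposure", model = "linear")
    nrow(select_instruments(res, 5e-6))
  }, numeric(1))
  expect_gte(mean(hits == 5), 0.95)
})

test_that("the partial F-statistic equals the squared t-statistic", {
  co <- valid_iv_cohort(n = 2000, theta = 0.2, seed = 61)
  ph <- co$phenotypes
  G <- geno_matrix(co$genotypes)
  covar <- withr::with_seed(62, cbind(age = rnorm(2000, 50, 10)))
  for (j in 1:5) {
    fit <- fit_linear(ph$exposure, cbind(dosage = G[, j], covar))
    tt <- with(fit$coefficients[2, ], estimate / se)
    expect_equal(f_statistic(G[, j], ph$exposure, covar), tt^2,
                 tolerance = 1e-9)
  }
})

test_that("F values track the strength arithmetic F ~ (n-p) R2/(1-R2)", {
  # strong instrument with partial R2 about 0.01 at n = 10,000 -> F near 100
  withr::with_seed(63, {
    gv <- rbinom(10000, 2, 0.3)
    x <- 0.154 * gv + rnorm(10000)  # var ratio ~ 0.01
    f <- f_statistic(gv, x)
    r2 <- summary(stats::lm(x ~ gv))$r.squared
    expect_equal(f, (10000 - 2) * r2 / (1 - r2), tolerance = 1e-6)
    expect_gt(f, 50)
    expect_lt(f, 180)
  })
  # null SNP rarely reaches F = 10 (central F tail)
  fs <- vapply(1:30, function(s) {
    withr::with_seed(700 + s, {
      gv <- rbinom(5000, 2, 0.3)
      f_statistic(gv, rnorm(5000))
    })
  }, numeric(1))
  expect_gte(mean(fs < 10), 0.97)
})

test_that("weak-instrument screening applies the inclusive F threshold", {
  co <- valid_iv_cohort(n = 2000, theta = 0, seed = 64)
  res <- gwas(co$genotypes, co$phenotypes, "exposure", model = "linear")
  cand <- dplyr::mutate(res, p = 1e-8)  # force all through selection
  ins_all <- screen_instruments(cand, co$genotypes, co$phenotypes, "exposure",
                                f_threshold = 0.5)
  expect_identical(nrow(ins_all), 5L)

  # boundary semantics on a synthetic F: keep >= 10, drop < 10
  fs <- ins_all$f_statistic
  ins10 <- screen_instruments(cand, co$genotypes, co$phenotypes, "exposure",
                              f_threshold = min(fs))
  expect_identical(nrow(ins10), 5L)  # F equal to the threshold is retained
  expect_error(
    screen_instruments(cand, co$genotypes, co$phenotypes, "exposure",
                       f_threshold = max(fs) + 1),
    "MR cannot proceed")
  survivors <- screen_instruments(cand, co$genotypes, co$phenotypes, "exposure",
                                  f_threshold = sort(fs)[3])
  expect_identical(nrow(survivors), 3L)
})
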