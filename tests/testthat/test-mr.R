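test_that("harmonization aligns, orients and validates instrument sets", {
  ins <- tibble::tibble(snp_id = c("a", "b"), beta_exposure = c(0.3, -0.2),
                        se_exposure = c(0.05, 0.04))
  out <- tibble::tibble(snp_id = c("b", "a"), beta = c(0.1, -0.06),
                        se = c(0.02, 0.03), status = "ok")
  h <- harmonize(ins, out)
  expect_identical(h$snp_id, c("a", "b"))
  expect_true(all(h$beta_exposure >= 0))
  # flip preserves the ratio
  expect_equal(h$beta_outcome / h$beta_exposure, c(-0.2, -0.5), tolerance = 1e-12)
  expect_identical(h$flipped, c(FALSE, TRUE))

  # already aligned input passes through unchanged
  ins2 <- tibble::tibble(snp_id = "a", beta_exposure = 0.3, se_exposure = 0.05)
  h2 <- harmonize(ins2, out)
  expect_equal(h2$beta_outcome, -0.06)

  expect_error(harmonize(tibble::tibble(snp_id = "zzz", beta_exposure = 1,
                                        se_exposure = 1), out), "zzz")
  out_bad <- dplyr::mutate(out, effect_allele = c("A", "C"))
  ins_al <- dplyr::mutate(ins, effect_allele = "A")
  expect_error(harmonize(ins_al, out_bad), "allele mismatch")
})

test_that("ratio estimates follow the elementwise quotient with delta SEs", {
  h <- tibble::tibble(snp_id = c("a", "b"), beta_exposure = c(0.5, 0.4),
                      se_exposure = c(0.1, 0.1), beta_outcome = c(0.1, 0),
                      se_outcome = c(0.02, 0.05))
  r <- ratio_estimates(h)
  expect_equal(r$ratio, c(0.2, 0))
  expect_equal(r$se_ratio, c(0.04, 0.125))
  # sign flip of a pair leaves the ratio unchanged
  h2 <- h
  h2$beta_exposure[1] <- -h2$beta_exposure[1]
  h2$beta_outcome[1] <- -h2$beta_outcome[1]
  expect_equal(ratio_estimates(h2)$ratio, r$ratio)
})

test_that("IVW reduces to known closed forms", {
  h1 <- tibble::tibble(snp_id = "a", beta_exposure = 0.4, se_exposure = 0.1,
                       beta_outcome = 0.12, se_outcome = 0.05)
  expect_equal(mr_ivw(h1)$estimate, 0.3, tolerance = 1e-12)

  h2 <- tibble::tibble(snp_id = c("a", "b"), beta_exposure = c(1, 1),
                       se_exposure = 0.1, beta_outcome = c(0.2, 0.4),
                       se_outcome = c(0.05, 0.05))
  expect_equal(mr_ivw(h2)$estimate, 0.3, tolerance = 1e-12)
})

test_that("IVW and MR-Egger match independent normal-equation oracles", {
  for (s in 1:20) {
    h <- random_harmonized(6, seed = 800 + s)
    w <- 1 / h$se_outcome^2

    ref_ivw <- wls_origin_oracle(h$beta_exposure, h$beta_outcome, w)
    fit_ivw <- mr_ivw(h)
    expect_equal(fit_ivw$estimate, ref_ivw$estimate, tolerance = 1e-10)
    expect_equal(fit_ivw$se, ref_ivw$se, tolerance = 1e-10)

    ref_egger <- wls_line_oracle(h$beta_exposure, h$beta_outcome, w)
    fit_egger <- mr_egger(h)
    expect_equal(fit_egger$estimate, ref_egger$slope, tolerance = 1e-10)
    expect_equal(fit_egger$se, ref_egger$se_slope, tolerance = 1e-10)
    expect_equal(fit_egger$intercept, ref_egger$intercept, tolerance = 1e-10)
    expect_equal(fit_egger$intercept_se, ref_egger$se_intercept, tolerance = 1e-10)
  }
})

test_that("random-effects IVW inflates but never shrinks the SE", {
  h <- random_harmonized(8, seed = 881)
  fixed <- mr_ivw(h, "fixed")
  rand <- mr_ivw(h, "multiplicative_random")
  expect_identical(fixed$estimate, rand$estimate)
  expect_gte(rand$se, fixed$se)
  h1 <- h[1, ]
  expect_warning(r1 <- mr_ivw(h1, "multiplicative_random"), "single instrument")
  expect_identical(r1$se, mr_ivw(h1, "fixed")$se)
})

test_that("MR-Egger recovers exact linear summary data", {
  withr::with_seed(91, {
    bx <- runif(5, 0.1, 0.6)
    h <- tibble::tibble(snp_id = letters[1:5], beta_exposure = bx,
                        se_exposure = 0.02, beta_outcome = 0.1 + 0.3 * bx,
                        se_outcome = runif(5, 0.02, 0.08))
  })
  e <- mr_egger(h)
  expect_equal(e$intercept, 0.1, tolerance = 1e-12)
  expect_equal(e$estimate, 0.3, tolerance = 1e-12)
  # exact fit: residual factor hits the floor of 1 (fixed-effect SEs)
  w <- 1 / h$se_outcome^2
  ref <- wls_line_oracle(h$beta_exposure, h$beta_outcome, w)
  expect_equal(e$se, ref$se_slope, tolerance = 1e-12)

  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("with equal weights through the origin, Egger slope matches IVW", {
  # data through the origin and identical outcome SEs: the Egger normal
  # equations coincide with through-origin WLS when the intercept estimate
  # vanishes
  bx <- c(0.2, 0.4, 0.6, 0.8)
  h <- tibble::tibble(snp_id = letters[1:4], beta_exposure = bx,
                      se_exposure = 0.02, beta_outcome = 0.25 * bx,
                      se_outcome = 0.05)
  e <- mr_egger(h)
  expect_equal(e$intercept, 0, tolerance = 1e-12)
  expect_equal(e$estimate, mr_ivw(h)$estimate, tolerance = 1e-9)
})

test_that("median estimators follow the cumulative-weight interpolation", {
  # equal weights, ratios {0.1, 0.2, 0.9}: cumulative weights 1/6, 3/6, 5/6
  # -> interpolation at 0.5 returns the middle ratio exactly
  h <- tibble::tibble(snp_id = c("a", "b", "c"),
                      beta_exposure = 1, se_exposure = 0.05,
                      beta_outcome = c(0.1, 0.2, 0.9), se_outcome = 0.05)
  sm <- mr_simple_median(h, n_boot = 100, seed = 1)
  expect_equal(sm$estimate, 0.2, tolerance = 1e-12)

  # equal weights -> weighted median identical to simple median
  wm <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(wm$estimate, sm$estimate, tolerance = 1e-12)

  # hand-walked unequal-weight interpolation
  ratios <- c(0.1, 0.3, 0.8)
  weights <- c(1, 2, 1)
  cw <- (cumsum(weights) - weights / 2) / sum(weights)  # 0.125, 0.5, 0.875
  expect_equal(cw[2], 0.5)
  h2 <- tibble::tibble(snp_id = c("a", "b", "c"), beta_exposure = 1,
                       se_exposure = 0.01,
                       beta_outcome = ratios,
                       se_outcome = 1 / sqrt(weights))
  wm2 <- mr_weighted_median(h2, n_boot = 100, seed = 1)
  expect_equal(wm2$estimate, 0.3, tolerance = 1e-12)

  # dominant-weight outlier pulls the estimate but stays within the
  # neighbouring order statistics
  h3 <- tibble::tibble(snp_id = c("a", "b", "c", "d"), beta_exposure = 1,
                       se_exposure = 0.01,
                       beta_outcome = c(0.2, 0.21, 0.19, 1.0),
                       se_outcome = c(0.3, 0.3, 0.3, 0.05))
  wm3 <- mr_weighted_median(h3, n_boot = 100, seed = 1)
  expect_gt(wm3$estimate, 0.21)
  expect_lte(wm3$estimate, 1.0)

  expect_error(mr_simple_median(h[1:2, ]), "at least 3")
})

test_that("median bootstrap SEs are seeded and shrink with the input SEs", {
  h <- random_harmonized(6, seed = 92)
  a <- mr_weighted_median(h, n_boot = 500, seed = 7)
  b <- mr_weighted_median(h, n_boot = 500, seed = 7)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(h, n_boot = 500, seed = 8)
  expect_false(identical(a$se, c_$se))

  # degenerate: all ratios equal, tiny SEs -> estimate exact, SE tiny
  h0 <- tibble::tibble(snp_id = letters[1:4], beta_exposure = c(0.2, 0.3, 0.4, 0.5),
                       se_exposure = 1e-6,
                       beta_outcome = 0.25 * c(0.2, 0.3, 0.4, 0.5),
                       se_outcome = 1e-6)
  d <- mr_simple_median(h0, n_boot = 200, seed = 1)
  expect_equal(d$estimate, 0.25, tolerance = 1e-9)
  expect_lt(d$se, 1e-4)
})

test_that("weighted median resists a minority of invalid instruments better than IVW", {
  # 2 of 5 instruments with large pleiotropic offsets; valid instruments
  # carry > 50% of the weight and agree on ratio 0.2
  bx <- c(0.3, 0.35, 0.4, 0.3, 0.35)
  by <- 0.2 * bx
  by[4:5] <- by[4:5] + 0.15  # invalid pair
  h <- tibble::tibble(snp_id = letters[1:5], beta_exposure = bx,
                      se_exposure = 0.02, beta_outcome = by,
                      se_outcome = 0.02)
  wm <- mr_weighted_median(h, n_boot = 500, seed = 3)
  ivw <- mr_ivw(h)
  expect_lt(abs(wm$estimate - 0.2), 3 * wm$se)
  expect_gt(abs(ivw$estimate - 0.2), abs(wm$estimate - 0.2))
})

test_that("estimator invariances: scale equivariance and orientation invariance", {
  h <- random_harmonized(7, seed = 95)
  ests <- function(hh, seed = 5) {
    c(ivw = mr_ivw(hh)$estimate,
      egger = mr_egger(hh)$estimate,
      sm = mr_simple_median(hh, n_boot = 50, seed = seed)$estimate,
      wm = mr_weighted_median(hh, n_boot = 50, seed = seed)$estimate)
  }
  base <- ests(h)

  # multiplying all exposure effects by c > 0 divides every estimate by c
  for (cc in c(0.5, 2, 10)) {
    hs <- h
    hs$beta_exposure <- hs$beta_exposure * cc
    hs$se_exposure <- hs$se_exposure * cc
    expect_equal(ests(hs), base / cc, tolerance = 1e-9)
  }

  # flipping the sign of any pair leaves estimates unchanged (after the
  # orientation step inside harmonize)
  ins <- tibble::tibble(snp_id = h$snp_id, beta_exposure = h$beta_exposure,
                        se_exposure = h$se_exposure)
  outs <- tibble::tibble(snp_id = h$snp_id, beta = h$beta_outcome,
                         se = h$se_outcome, status = "ok")
  ins_f <- ins; outs_f <- outs
  ins_f$beta_exposure[3] <- -ins_f$beta_exposure[3]
  outs_f$beta[3] <- -outs_f$beta[3]
  expect_equal(ests(harmonize(ins_f, outs_f)), ests(harmonize(ins, outs)),
               tolerance = 1e-12)
})

test_that("MRResult CIs and p-values obey the stated normal relations", {
  for (s in 1:5) {
    h <- random_harmonized(5, seed = 900 + s)
    res <- mr_all(h, seed = s, n_boot = 100)
    ok <- res[res$status == "ok", ]
    expect_equal(ok$ci_lower, ok$estimate - 1.959964 * ok$se, tolerance = 1e-9)
    expect_equal(ok$ci_upper, ok$estimate + 1.959964 * ok$se, tolerance = 1e-9)
    expect_equal(ok$p, 2 * pnorm(-abs(ok$estimate / ok$se)), tolerance = 1e-10)
  }
})

test_that("odds-ratio conversion exponentiates estimate and CI", {
  h <- tibble::tibble(snp_id = "a", beta_exposure = 1, se_exposure = 0.05,
                      beta_outcome = 0, se_outcome = 0.05)
  or0 <- to_odds_ratio(mr_ivw(h))
  expect_equal(or0$or, 1)

  r <- tibble::tibble(method = "Weighted median", estimate = 0.134, se = 0.009,
                      ci_lower = 0.134 - 1.959964 * 0.009,
                      ci_upper = 0.134 + 1.959964 * 0.009,
                      p = 2 * pnorm(-abs(0.134 / 0.009)))
  or <- to_odds_ratio(r)
  expect_equal(or$or, exp(0.134), tolerance = 1e-12)
  expect_equal(unname(unlist(or[c("or_ci_lower", "or_ci_upper")])),
               exp(c(r$ci_lower, r$ci_upper)), tolerance = 1e-12)
  expect_lt(or$or_ci_lower, or$or_ci_upper)
})

test_that("mr_all runs all four methods, reports the intercept row, and is seeded", {
  # pleiotropy-free exact-line fixture: all four estimates agree
  bx <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  h <- tibble::tibble(snp_id = letters[1:5], beta_exposure = bx,
                      se_exposure = 0.01, beta_outcome = 0.25 * bx,
                      se_outcome = 0.02)
  res <- mr_all(h, seed = 10, n_boot = 200)
  expect_identical(res$method,
                   c("IVW", "Simple median", "Weighted median", "MR-Egger",
                     "(Intercept)"))
  ests <- res$estimate[res$method %in% c("IVW", "Simple median",
                                         "Weighted median", "MR-Egger")]
  expect_equal(ests, rep(0.25, 4), tolerance = 1e-9)

  res2 <- mr_all(h, seed = 10, n_boot = 200)
  expect_identical(res, res2)

  # partial failure: 2 instruments -> medians and Egger report status, IVW runs
  resp <- mr_all(h[1:2, ], seed = 1, n_boot = 50)
  expect_identical(resp$status[resp$method == "IVW"], "ok")
  expect_true(any(grepl("at least 3", resp$status)))
  expect_false(anyNA(resp$estimate[resp$method == "IVW"]))
})
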