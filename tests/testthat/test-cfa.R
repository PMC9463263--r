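test_that("one twin per pair is selected reproducibly from complete pairs", {
  d <- simulate_twins(twin_sim_config(seed = 2))
  t1 <- select_one_twin_per_pair(d, seed = 10)
  t2 <- select_one_twin_per_pair(d, seed = 10)
  t3 <- select_one_twin_per_pair(d, seed = 11)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  # every family with at least one fully observed twin contributes once,
  # and the selected individual is always complete on all traits
  expect_equal(nrow(t1), sum(reference_group_sizes()$pairs))
  expect_true(all(stats::complete.cases(t1)))
  expect_equal(anyDuplicated(t1$family_id), 0L)
  # among families with two complete twins the choice depends on the seed
  expect_false(all(t1$twin == t3$twin))
  expect_true(all(psqi_components() %in% colnames(t1)))
})

test_that("an exact one-factor covariance yields perfect fit indices", {
  lam <- c(0.7, 0.6, 0.5, 0.8, 0.4, 0.55, 0.65)
  names(lam) <- psqi_components()
  S <- tcrossprod(lam) + diag(1 - lam^2)
  dimnames(S) <- list(psqi_components(), psqi_components())
  f <- fit_cfa(psqi_cfa_specs()$one_factor, S = S, n = 500)
  expect_equal(f$indices$chi2, 0, tolerance = 1e-5)
  expect_equal(f$indices$RMSEA, 0)
  expect_equal(f$indices$CFI, 1)
  expect_lt(f$indices$SRMR, 1e-4)
  # loadings recovered up to sign
  got <- abs(f$loadings[f$loadings != 0])
  expect_equal(unname(got), unname(lam), tolerance = 1e-4)
})

test_that("three correlated factors with unit correlations equal one factor", {
  lam <- c(0.7, 0.6, 0.5, 0.8, 0.4, 0.55, 0.65)
  names(lam) <- psqi_components()
  S <- tcrossprod(lam) + diag(1 - lam^2)
  dimnames(S) <- list(psqi_components(), psqi_components())
  f1 <- fit_cfa(psqi_cfa_specs()$one_factor, S = S, n = 500)
  spc <- psqi_cfa_specs()$cole_three_factor
  spc$factor_correlations <- "unit"
  f3 <- fit_cfa(spc, S = S, n = 500)
  expect_equal(f3$indices$chi2, f1$indices$chi2, tolerance = 1e-4)
})

test_that("fit indices match hand-computed formulas", {
  idx <- fit_indices(chi2 = 40, df = 10, chi2_b = 400, df_b = 21,
                     n = 500, n_params = 21, srmr = 0.05)
  expect_equal(idx$RMSEA, sqrt((40 - 10) / (10 * 499)))
  expect_equal(idx$CFI, 1 - (40 - 10) / (400 - 21))
  expect_equal(idx$TLI, ((400 / 21) - (40 / 10)) / ((400 / 21) - 1))
  expect_equal(idx$BIC, 40 + 21 * log(500))
  expect_equal(idx$SRMR, 0.05)
  # the 90% RMSEA interval brackets the point estimate
  expect_lt(idx$RMSEA_lo, idx$RMSEA)
  expect_gt(idx$RMSEA_hi, idx$RMSEA)
  # a chi2 below its df truncates RMSEA (and its lower limit) at zero
  idx0 <- fit_indices(chi2 = 8, df = 10, chi2_b = 400, df_b = 21,
                      n = 500, n_params = 21)
  expect_equal(idx0$RMSEA, 0)
  expect_equal(idx0$RMSEA_lo, 0)
})

test_that("RMSEA confidence limits invert the noncentral chi-square", {
  idx <- fit_indices(chi2 = 40, df = 10, chi2_b = 400, df_b = 21,
                     n = 500, n_params = 21)
  # at the limits, the observed chi2 sits at the 95th / 5th percentile
  lam_hi <- idx$RMSEA_hi^2 * 10 * 499
  lam_lo <- idx$RMSEA_lo^2 * 10 * 499
  expect_equal(stats::pchisq(40, 10, ncp = lam_hi), 0.05, tolerance = 1e-4)
  expect_equal(stats::pchisq(40, 10, ncp = lam_lo), 0.95, tolerance = 1e-4)
})

test_that("CFA results are invariant to rescaling the input covariance", {
  set.seed(8)
  d <- simulate_twins(twin_sim_config(seed = 8))
  one <- select_one_twin_per_pair(d, seed = 1)
  f <- fit_cfa(psqi_cfa_specs()$one_factor, table = one)
  sc <- diag(c(2, 0.5, 3, 1, 4, 0.8, 1.5))
  S <- stats::cov(as.matrix(one[, psqi_components()]))
  S2 <- sc %*% S %*% sc
  dimnames(S2) <- dimnames(S)
  f2 <- fit_cfa(psqi_cfa_specs()$one_factor, S = S2, n = nrow(one))
  # fit statistics are scale-free even though loadings are not
  expect_equal(f2$indices$chi2, f$indices$chi2, tolerance = 1e-4)
  expect_equal(f2$indices$CFI, f$indices$CFI, tolerance = 1e-5)
  expect_equal(f2$indices$SRMR, f$indices$SRMR, tolerance = 1e-5)
})

test_that("residual covariances absorb local dependence", {
  # data with a latent factor plus one extra correlated residual pair:
  # the residual-correlated model must fit better and estimate that entry
  lam <- c(0.7, 0.6, 0.5, 0.8, 0.4, 0.55, 0.65)
  names(lam) <- psqi_components()
  S <- tcrossprod(lam) + diag(1 - lam^2)
  dimnames(S) <- list(psqi_components(), psqi_components())
  S["duration", "efficiency"] <- S["duration", "efficiency"] + 0.15
  S["efficiency", "duration"] <- S["duration", "efficiency"]
  plain <- fit_cfa(psqi_cfa_specs()$one_factor, S = S, n = 600)
  resid <- fit_cfa(cfa_spec(structure = list(sleep_quality = psqi_components()),
                            residual_pairs = list(c("duration", "efficiency"))),
                   S = S, n = 600)
  expect_lt(resid$indices$chi2, plain$indices$chi2)
  expect_lt(resid$indices$BIC, plain$indices$BIC)
  expect_equal(resid$residual_cov["duration", "efficiency"], 0.15,
               tolerance = 0.02)
})

test_that("malformed CFA specifications are rejected", {
  d <- simulate_twins(twin_sim_config(seed = 2))
  one <- select_one_twin_per_pair(d, seed = 1)
  expect_error(fit_cfa(cfa_spec(structure = list(f = c("latency",
                                                       "nonexistent"))),
                       table = one),
               "nonexistent")
  expect_error(cfa_spec(structure = list(f1 = "latency",
                                         f2 = c("latency", "duration"))),
               "exactly one")
  expect_error(cfa_spec(residual_pairs = list(c("latency", "latency"))),
               "distinct")
  expect_error(fit_indices(chi2 = 40, df = 0, chi2_b = 400, df_b = 21,
                           n = 500, n_params = 21), "df")
})
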