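test_that("rectangle probabilities match brute-force quadrature", {
  s2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  cases <- list(list(l = c(-0.5, -1), u = c(1, 0.3)),
                list(l = c(-Inf, 0), u = c(0, Inf)),
                list(l = c(0.2, 0.2), u = c(2.5, 1.4)))
  for (cs in cases) {
    expect_equal(mvn_rectangle(cs$l, cs$u, s2),
                 oracle_rectangle2(cs$l, cs$u, s2), tolerance = 1e-6)
  }
  s3 <- random_spd(3, 4)
  expect_equal(mvn_rectangle(c(-1, -0.5, -Inf), c(0.5, 1.2, 0.8), s3),
               oracle_rectangle3(c(-1, -0.5, -Inf), c(0.5, 1.2, 0.8), s3),
               tolerance = 1e-6)
  # nonzero mean shifts the box
  expect_equal(mvn_rectangle(c(-0.5, -1), c(1, 0.3), s2, mean = c(0.3, -0.2)),
               oracle_rectangle2(c(-0.5, -1), c(1, 0.3), s2,
                                 mean = c(0.3, -0.2)),
               tolerance = 1e-6)
})

test_that("rectangle probabilities over all categories sum to one", {
  # exhaustive conservation for two ordinal traits with four categories
  tau <- list(c(-0.84, 0.25, 1.04), c(-0.67, 0.43, 1.28))
  s <- matrix(c(1, 0.45, 0.45, 1), 2)
  total <- 0
  for (i in 1:4) for (j in 1:4) {
    lo <- c(c(-Inf, tau[[1]])[i], c(-Inf, tau[[2]])[j])
    hi <- c(c(tau[[1]], Inf)[i], c(tau[[2]], Inf)[j])
    total <- total + mvn_rectangle(lo, hi, s)
  }
  expect_equal(total, 1, tolerance = 1e-8)
})

test_that("continuous pair log-likelihood matches the closed form", {
  tr <- "duration"
  one <- function(v) matrix(v, dimnames = list(tr, tr))
  vc <- variance_components(kind = "AE", A = one(0.3^2), E = one(1 - 0.3^2))
  mt <- mean_threshold_model(tr, intercepts = c(duration = 0))
  sp <- toy_specs(tr)
  rec <- data.frame(family_id = 1L, zygosity = "MZf", age = 50,
                    sex1 = 0L, sex2 = 0L, duration_1 = 0, duration_2 = 0)
  # MZ pair at the mean: bivariate normal density with correlation a2
  expect_equal(pair_loglik(rec, vc, mt, specs = sp),
               mvtnorm::dmvnorm(c(0, 0),
                                sigma = matrix(c(1, 0.09, 0.09, 1), 2),
                                log = TRUE),
               tolerance = 1e-10)
  rec2 <- rec; rec2$duration_1 <- 0.7; rec2$duration_2 <- -0.4
  rec2$zygosity <- "DZm"
  expect_equal(pair_loglik(rec2, vc, mt, specs = sp),
               mvtnorm::dmvnorm(c(0.7, -0.4),
                                sigma = matrix(c(1, 0.045, 0.045, 1), 2),
                                log = TRUE),
               tolerance = 1e-10)
})

test_that("a single ordinal observation at a zero threshold gives log(1/2)", {
  tr <- "medication"
  one <- function(v) matrix(v, dimnames = list(tr, tr))
  vc <- variance_components(kind = "AE", A = one(0.4), E = one(0.6))
  sp <- psqi_specs()[6, ]; sp$n_cat <- 2L
  mt <- mean_threshold_model(tr, thresholds = list(medication = 0))
  rec <- data.frame(family_id = 1L, zygosity = "MZf", age = 50,
                    sex1 = 0L, sex2 = 0L,
                    medication_1 = 0L, medication_2 = NA_integer_)
  expect_equal(pair_loglik(rec, vc, mt, specs = sp), log(0.5),
               tolerance = 1e-10)
})

test_that("mixed continuous-ordinal pair likelihood matches quadrature", {
  # one continuous and one ordinal trait per twin, complete MZ pair:
  # verify against density x conditional rectangle computed by the oracle
  trs <- c("duration", "medication")
  A <- matrix(c(0.3, 0.1, 0.1, 0.4), 2, 2, dimnames = list(trs, trs))
  E <- matrix(c(0.7, 0.08, 0.08, 0.6), 2, 2, dimnames = list(trs, trs))
  vc <- variance_components(kind = "AE", A = A, E = E)
  sp <- psqi_specs()[c(2, 6), ]
  tau <- c(-0.5, 0.4, 1.2)
  mt <- mean_threshold_model(trs, intercepts = c(duration = 0),
                             thresholds = list(medication = tau))
  rec <- data.frame(family_id = 1L, zygosity = "MZf", age = 50,
                    sex1 = 0L, sex2 = 0L,
                    duration_1 = 0.5, duration_2 = -0.2,
                    medication_1 = 1L, medication_2 = 2L)
  sig <- expected_twin_covariance(vc, "MZ")
  # order in sig: duration_1, medication_1, duration_2, medication_2
  ci <- c(1, 3); oi <- c(2, 4)
  scc <- sig[ci, ci]; sco <- sig[ci, oi]; soo <- sig[oi, oi]
  y <- c(0.5, -0.2)
  cm <- drop(crossprod(sco, solve(scc, y)))
  cv <- soo - crossprod(sco, solve(scc, sco))
  bounds <- cbind(c(tau[1], tau[2]), c(tau[2], tau[3]))
  expected <- mvtnorm::dmvnorm(y, sigma = scc, log = TRUE) +
    log(oracle_rectangle2(bounds[, 1], bounds[, 2],
                          sigma = cv, mean = cm))
  expect_equal(pair_loglik(rec, vc, mt, specs = sp), expected,
               tolerance = 1e-6)
})

test_that("an incomplete pair marginalizes to the singleton likelihood", {
  d <- simulate_twins(toy_config(seed = 9))
  vc <- toy_components()
  mt <- mean_threshold_model(c("duration", "efficiency"),
                             intercepts = c(duration = 0, efficiency = 0))
  rec <- d$data[1, ]
  rec$duration_2 <- NA_real_; rec$efficiency_2 <- NA_real_
  y <- c(rec$duration_1, rec$efficiency_1)
  expect_equal(pair_loglik(rec, vc, mt, specs = toy_specs()),
               mvtnorm::dmvnorm(y, sigma = total_covariance(vc), log = TRUE),
               tolerance = 1e-10)
})

test_that("the -2LL is invariant to swapping twin 1 and twin 2", {
  d <- simulate_twins(toy_config(seed = 15, n_mz = 150L, n_dz = 150L))
  m <- build_multivariate("AE", specs = toy_specs())
  swap <- d$data
  for (tr in c("duration", "efficiency")) {
    a <- swap[[paste0(tr, "_1")]]
    swap[[paste0(tr, "_1")]] <- swap[[paste0(tr, "_2")]]
    swap[[paste0(tr, "_2")]] <- a
  }
  s <- swap$sex1; swap$sex1 <- swap$sex2; swap$sex2 <- s
  dswap <- twin_dataset(swap, toy_specs())
  f1 <- fit_twin_model(m, d, restarts = 0)
  f2 <- fit_twin_model(m, dswap, restarts = 0, start = f1$optim$par)
  expect_equal(f2$minus2LL, f1$minus2LL, tolerance = 1e-6)
})

test_that("nested-model comparison computes the likelihood-ratio test", {
  fake <- function(m2, k) structure(list(minus2LL = m2, n_params = k,
                                         AIC = m2 + 2 * k),
                                    class = "twin_fit")
  cmp <- compare_fits(fake(100, 5), fake(103.84, 4))
  expect_equal(cmp$chi2, 3.84)
  expect_equal(cmp$df, 1L)
  expect_equal(cmp$p, stats::pchisq(3.84, 1, lower.tail = FALSE))
  same <- compare_fits(fake(100, 5), fake(100, 5))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  # a nested model cannot beat the full model: that signals a failed fit
  expect_error(compare_fits(fake(100, 5), fake(90, 4)), "refit")
})

test_that("univariate AE fit recovers h2 and beats the E-only model", {
  tr <- "duration"
  one <- function(v) matrix(v, dimnames = list(tr, tr))
  vc <- variance_components(kind = "AE", A = one(0.5), E = one(0.5))
  gs <- data.frame(zygosity = c("MZf", "DZf"), pairs = c(1000L, 1000L),
                   complete = c(1000L, 1000L))
  cfg <- twin_sim_config(components = vc, specs = toy_specs(tr),
                         thresholds = list(), skew_traits = character(0),
                         group_sizes = gs, seed = 41)
  d <- simulate_twins(cfg)
  fae <- fit_twin_model(build_multivariate("AE", specs = toy_specs(tr)), d,
                        restarts = 0)
  fe <- fit_twin_model(build_multivariate("E", specs = toy_specs(tr)), d,
                       restarts = 0)
  expect_true(fae$converged)
  expect_equal(standardize_components(fae$vc)[1, "h2"], 0.5,
               tolerance = 0.06, ignore_attr = TRUE)
  cmp <- compare_fits(fae, fe)
  expect_lt(cmp$p, 1e-10)
})

test_that("ordinal liability fit recovers threshold and heritability", {
  tr <- "medication"
  one <- function(v) matrix(v, dimnames = list(tr, tr))
  vc <- variance_components(kind = "AE", A = one(0.45), E = one(0.55))
  sp <- psqi_specs()[6, ]
  gs <- data.frame(zygosity = c("MZf", "DZf"), pairs = c(700L, 700L),
                   complete = c(700L, 700L))
  tau <- c(-0.6, 0.3, 1.0)
  cfg <- twin_sim_config(components = vc, specs = sp,
                         thresholds = list(medication = tau),
                         skew_traits = character(0), group_sizes = gs,
                         seed = 19)
  d <- simulate_twins(cfg)
  fit <- fit_twin_model(build_multivariate("AE", specs = sp), d,
                        restarts = 1, seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(standardize_components(fit$vc)[1, "h2"] - 0.45), 0.12)
  est_tau <- fit$mt$thresholds$medication
  expect_lt(max(abs(est_tau - tau)), 0.12)
})

test_that("profile confidence interval brackets the point estimate", {
  d <- simulate_twins(toy_config(seed = 25))
  m <- build_multivariate("AE", specs = toy_specs())
  fit <- fit_twin_model(m, d, restarts = 0)
  h2_of <- function(par) {
    u <- m$unpack(par)
    u$vc$A[1, 1] / (u$vc$A[1, 1] + u$vc$E[1, 1])
  }
  ci <- profile_ci(fit, d, what = h2_of, level = 0.95, bounds = c(0, 1))
  h2 <- standardize_components(fit$vc)["duration", "h2"]
  expect_equal(ci$estimate, h2, ignore_attr = TRUE)
  expect_lt(ci$lo, h2)
  expect_gt(ci$hi, h2)
  expect_lt(ci$hi - ci$lo, 0.5)
  expect_false(ci$lo_boundary || ci$hi_boundary)
})
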