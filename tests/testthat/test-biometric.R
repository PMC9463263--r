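test_that("expected twin covariance uses the classical relatedness coefficients", {
  tr <- c("duration", "efficiency")
  A <- matrix(c(0.3, 0.1, 0.1, 0.2), 2, 2, dimnames = list(tr, tr))
  E <- matrix(c(0.7, 0.05, 0.05, 0.8), 2, 2, dimnames = list(tr, tr))
  vc <- variance_components(kind = "AE", A = A, E = E)
  mz <- expected_twin_covariance(vc, "MZ")
  dz <- expected_twin_covariance(vc, "DZ")
  expect_equal(dim(mz), c(4L, 4L))
  # within-twin blocks are the total covariance for both zygosities
  expect_equal(mz[1:2, 1:2], A + E, ignore_attr = TRUE)
  expect_equal(dz[3:4, 3:4], A + E, ignore_attr = TRUE)
  # cross-twin blocks carry the genetic coefficient: 1 for MZ, 1/2 for DZ
  expect_equal(mz[1:2, 3:4], A, ignore_attr = TRUE)
  expect_equal(dz[1:2, 3:4], 0.5 * A, ignore_attr = TRUE)
  expect_equal(mz[1:2, 3:4] - dz[1:2, 3:4], 0.5 * A, ignore_attr = TRUE)
})

test_that("dominance enters the DZ cross-block with coefficient 1/4", {
  tr <- "duration"
  one <- function(v) matrix(v, 1, 1, dimnames = list(tr, tr))
  vc <- variance_components(kind = "ADE", A = one(0.2), CorD = one(0.2),
                            E = one(0.6))
  expect_equal(expected_twin_covariance(vc, "MZ")[1, 2], 0.4)
  expect_equal(expected_twin_covariance(vc, "DZ")[1, 2],
               0.5 * 0.2 + 0.25 * 0.2)
  # MZ - DZ cross-covariance identity for ADE: 0.5 A + 0.75 D
  expect_equal(expected_twin_covariance(vc, "MZ")[1, 2] -
                 expected_twin_covariance(vc, "DZ")[1, 2],
               0.5 * 0.2 + 0.75 * 0.2)
})

test_that("standardization divides by total variance and sums to one", {
  tr <- c("duration", "efficiency")
  A <- matrix(c(0.5, 0.1, 0.1, 0.42), 2, 2, dimnames = list(tr, tr))
  E <- matrix(c(1.5, 0.2, 0.2, 1.58), 2, 2, dimnames = list(tr, tr))
  vc <- variance_components(kind = "AE", A = A, E = E)
  std <- standardize_components(vc)
  expect_equal(std[, "h2"], c(duration = 0.25, efficiency = 0.21))
  expect_equal(unname(std[, "h2"] + std[, "e2"]), c(1, 1))
})

test_that("etiological correlations invert to the component covariances", {
  # round-trip: build A from (h2, rA) on unit-variance traits and recover
  h2 <- c(duration = 0.25, efficiency = 0.21)
  rA <- 0.69
  a12 <- rA * sqrt(prod(h2))
  A <- matrix(c(h2[1], a12, a12, h2[2]), 2, 2,
              dimnames = list(names(h2), names(h2)))
  E <- diag(1 - h2); dimnames(E) <- dimnames(A)
  E[1, 2] <- E[2, 1] <- 0.62 * sqrt(prod(1 - h2))
  vc <- variance_components(kind = "AE", A = A, E = E)
  ec <- etiological_correlations(vc)
  expect_equal(ec$rA[1, 2], 0.69)
  expect_equal(ec$rE[1, 2], 0.62)
  expect_equal(diag(ec$rA), c(duration = 1, efficiency = 1))
})

test_that("etiological correlations are undefined for a zero component", {
  tr <- c("duration", "efficiency")
  A <- matrix(c(0, 0, 0, 0.3), 2, 2, dimnames = list(tr, tr))
  E <- matrix(c(1, 0.1, 0.1, 0.7), 2, 2, dimnames = list(tr, tr))
  vc <- variance_components(kind = "AE", A = A, E = E)
  ec <- etiological_correlations(vc)
  expect_true(is.na(ec$rA[1, 2]))
})

test_that("phenotypic-correlation decomposition matches hand-computed shares", {
  d <- decompose_phenotypic_correlation(h2_i = 0.21, h2_j = 0.25,
                                        e2_i = 0.79, e2_j = 0.75,
                                        rA_ij = 0.69, rE_ij = 0.62)
  expect_equal(d$contribA, 0.69 * sqrt(0.21 * 0.25))
  expect_equal(d$contribE, 0.62 * sqrt(0.79 * 0.75))
  expect_equal(d$rPH, d$contribA + d$contribE)
  expect_equal(d$propA + d$propE, 1)
  expect_false(d$mixed_sign)
})

test_that("opposite-sign contributions are flagged and shares withheld", {
  # genetic and environmental contributions of opposite sign: reporting
  # proportions of a small net correlation would be misleading
  d <- decompose_phenotypic_correlation(h2_i = 0.40, h2_j = 0.25,
                                        e2_i = 0.60, e2_j = 0.75,
                                        rA_ij = -0.25, rE_ij = 0.03)
  expect_lt(d$contribA, 0)
  expect_gt(d$contribE, 0)
  expect_true(d$mixed_sign)
  expect_true(is.na(d$propA) && is.na(d$propE))
  expect_equal(round(d$contribE, 2), 0.02)
})

test_that("decomposition reconstructs the phenotypic correlation matrix", {
  # conservation: standardize -> correlate -> decompose must return the
  # correlation implied by the total covariance, for random AE structures
  for (seed in 1:5) {
    s <- random_spd(3, seed)
    a <- 0.2 + 0.4 * stats::runif(3)
    A <- random_spd(3, seed + 100) * tcrossprod(sqrt(a))
    E <- s - A
    if (min(eigen(E, symmetric = TRUE, only.values = TRUE)$values) < 0.01)
      next
    tr <- c("latency", "duration", "efficiency")
    dimnames(A) <- dimnames(E) <- list(tr, tr)
    vc <- variance_components(kind = "AE", A = A, E = E)
    std <- standardize_components(vc)
    ec <- etiological_correlations(vc)
    rph_expected <- stats::cov2cor(A + E)
    for (i in 2:3) for (j in 1:(i - 1)) {
      d <- decompose_phenotypic_correlation(
        std[i, "h2"], std[j, "h2"], std[i, "e2"], std[j, "e2"],
        ec$rA[i, j], ec$rE[i, j])
      expect_equal(d$rPH, rph_expected[i, j], tolerance = 1e-10)
    }
  }
})

test_that("reference estimates are internally consistent and positive definite", {
  ref <- psqi_reference_estimates()
  expect_equal(unname(ref$h2["medication"]), 0.40)
  expect_true(all(ref$h2 > 0 & ref$h2 < 1))
  expect_equal(ref$rA, t(ref$rA))
  vc <- psqi_reference_components()
  sig <- total_covariance(vc)
  expect_gt(min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values), 0)
  # unit-variance construction: the diagonal heritabilities round-trip
  expect_equal(standardize_components(vc)[, "h2"], ref$h2, tolerance = 1e-12)
  ec <- etiological_correlations(vc)
  expect_equal(ec$rA, ref$rA, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("decomposition table carries proportions for every trait pair", {
  tab <- decomposition_table(psqi_reference_components())
  expect_s3_class(tab, "decomposition_table")
  pairs <- tab$pairs
  expect_equal(nrow(pairs), choose(7, 2))
  ok <- !pairs$mixed_sign
  expect_true(all(abs(pairs$propA[ok] + pairs$propE[ok] - 1) < 1e-12))
})
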