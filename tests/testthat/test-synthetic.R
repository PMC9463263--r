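test_that("the generator is byte-identical under reseeding", {
  d1 <- simulate_twins(twin_sim_config(seed = 7))
  d2 <- simulate_twins(twin_sim_config(seed = 7))
  d3 <- simulate_twins(twin_sim_config(seed = 8))
  expect_identical(d1$data, d2$data)
  expect_false(identical(d1$data, d3$data))
})

test_that("group sizes, ages and sex composition follow the configuration", {
  d <- simulate_twins(twin_sim_config(seed = 3))
  gs <- reference_group_sizes()
  tab <- table(d$data$zygosity)
  expect_equal(as.integer(tab[gs$zygosity]), gs$pairs)
  expect_equal(nrow(d$data), sum(gs$pairs))
  expect_true(all(d$data$age >= 43 & d$data$age <= 71))
  expect_equal(mean(d$data$age), 53.7, tolerance = 0.05)
  # DOS pairs contain exactly one male; same-sex groups match their label
  dos <- d$data[d$data$zygosity == "DOS", ]
  expect_true(all(dos$sex1 + dos$sex2 == 1))
  expect_true(all(d$data$sex1[d$data$zygosity == "MZm"] == 1))
  expect_true(all(d$data$sex2[d$data$zygosity == "DZf"] == 0))
  # incomplete pairs have twin 2 missing on all traits
  n_complete <- sum(stats::complete.cases(
    d$data[, paste0(psqi_components(), "_2")]))
  expect_equal(n_complete, sum(gs$complete))
})

test_that("a pure-E truth yields near-zero cross-twin correlations", {
  tr <- c("duration", "efficiency")
  E <- diag(2); dimnames(E) <- list(tr, tr)
  vc <- variance_components(kind = "E", E = E)
  gs <- data.frame(zygosity = c("MZf", "DZf"), pairs = c(1500L, 1500L),
                   complete = c(1500L, 1500L))
  cfg <- twin_sim_config(components = vc, specs = toy_specs(tr),
                         thresholds = list(), skew_traits = character(0),
                         group_sizes = gs, seed = 11)
  ct <- cross_twin_correlations(simulate_twins(cfg))
  expect_true(all(abs(ct$r) < 0.06))
})

test_that("cross-twin correlations recover a univariate AE truth", {
  # h2 = 0.5 implies rMZ = 0.50 and rDZ = 0.25
  tr <- "duration"
  one <- function(v) matrix(v, dimnames = list(tr, tr))
  vc <- variance_components(kind = "AE", A = one(0.5), E = one(0.5))
  sp <- toy_specs(tr)
  gs <- data.frame(zygosity = c("MZf", "DZf"), pairs = c(5000L, 5000L),
                   complete = c(5000L, 5000L))
  cfg <- twin_sim_config(components = vc, specs = sp, thresholds = list(),
                         skew_traits = character(0), group_sizes = gs,
                         seed = 23)
  ct <- cross_twin_correlations(simulate_twins(cfg))
  expect_lt(abs(ct$r[ct$class == "MZ"] - 0.50), 0.03)
  expect_lt(abs(ct$r[ct$class == "DZ"] - 0.25), 0.04)
})

test_that("DZ cross-twin correlation converges to half the MZ value", {
  # property: under an AE truth the DZ/MZ ratio approaches 1/2 as n grows
  tr <- "duration"
  one <- function(v) matrix(v, dimnames = list(tr, tr))
  vc <- variance_components(kind = "AE", A = one(0.6), E = one(0.4))
  err <- sapply(c(500L, 2000L, 8000L), function(n) {
    gs <- data.frame(zygosity = c("MZf", "DZf"), pairs = c(n, n),
                     complete = c(n, n))
    cfg <- twin_sim_config(components = vc, specs = toy_specs(tr),
                           thresholds = list(), skew_traits = character(0),
                           group_sizes = gs, seed = 31L + n)
    ct <- cross_twin_correlations(simulate_twins(cfg))
    abs(ct$r[ct$class == "DZ"] / ct$r[ct$class == "MZ"] - 0.5)
  })
  expect_lt(err[3], 0.10)
  expect_lt(err[3], err[1])
})

test_that("polychoric correlation recovers thresholds and rho", {
  set.seed(99)
  n <- 10000L
  rho <- 0.55
  z <- matrix(stats::rnorm(2 * n), ncol = 2)
  z[, 2] <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
  tx <- c(-0.8, 0.3, 1.1); ty <- c(-0.3, 0.6, 1.5)
  x <- findInterval(z[, 1], tx); y <- findInterval(z[, 2], ty)
  pc <- polychoric_correlation(x, y, levels_x = 0:3, levels_y = 0:3)
  expect_equal(pc$rho, rho, tolerance = 0.03)
  expect_equal(pc$tau_x, tx, tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(pc$tau_y, ty, tolerance = 0.1, ignore_attr = TRUE)
})

test_that("a trait correlated with itself has cross-twin correlation one", {
  d <- simulate_twins(toy_config(seed = 5))
  dd <- d$data
  dd$duration_2 <- dd$duration_1
  dd$efficiency_2 <- dd$efficiency_1
  ct <- cross_twin_correlations(twin_dataset(dd, toy_specs()))
  expect_equal(ct$r, rep(1, nrow(ct)), tolerance = 1e-12)
})

test_that("Falconer screening reproduces textbook cases", {
  f <- falconer_estimates(0.5, 0.25)
  expect_equal(f$a2, 0.5)
  expect_equal(f$c2, 0)
  expect_equal(f$e2, 0.5)
  expect_false(f$out_of_band)

  f2 <- falconer_estimates(0.35, 0.14)
  expect_equal(f2$a2, 0.42)
  expect_equal(f2$recommendation, "ADE")
  expect_true(f2$out_of_band)  # implied c2 = -0.07 is reported, not clipped
  expect_equal(f2$c2, -0.07)

  f3 <- falconer_estimates(0.2, 0.2)
  expect_equal(f3$recommendation, "ACE")
  expect_equal(f3$a2, 0)
  expect_equal(f3$c2, 0.2)
})

test_that("skewed traits are generated positive and right-skewed", {
  d <- simulate_twins(twin_sim_config(seed = 13))
  lat <- d$data$latency_1
  expect_true(all(lat > 0))
  skew <- function(v) mean(((v - mean(v)) / stats::sd(v))^3)
  expect_gt(skew(lat), 0.5)
  # log(x + 1) then standardizing restores near-symmetry
  expect_lt(abs(skew(log1_transform(lat))), abs(skew(lat)))
})

test_that("ordinal traits take exactly the configured categories", {
  d <- simulate_twins(twin_sim_config(seed = 17))
  for (tr in c("quality", "medication", "daytime")) {
    v <- d$data[[paste0(tr, "_1")]]
    expect_true(all(v %in% 0:3))
    expect_gt(length(unique(v)), 2L)
  }
})
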