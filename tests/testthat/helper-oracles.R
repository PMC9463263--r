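# Brute-force oracles used to cross-check the analytic likelihood code.
# These deliberately use a different algorithm (tensor-product Simpson
# quadrature over conditional normal CDFs) than the production path
# (mvtnorm), so agreement is evidence of correctness, not of shared bugs.

# Simpson weights on a uniform grid with an odd number of points.
simpson_weights <- function(n, h) {
  w <- rep(c(4, 2), length.out = n - 2L)
  h / 3 * c(1, w[-(n - 2L)], 4, 1)
}

# P(l <= X <= u) for a bivariate normal via 1-D quadrature over x1 of
# phi(x1) * [Phi(.) - Phi(.)] with the conditional law of x2 | x1.
oracle_rectangle2 <- function(lower, upper, sigma, mean = c(0, 0),
                              n_grid = 4001L, span = 8.5) {
  s1 <- sqrt(sigma[1, 1]); s2 <- sqrt(sigma[2, 2])
  rho <- sigma[1, 2] / (s1 * s2)
  lo <- max(lower[1], mean[1] - span * s1)
  hi <- min(upper[1], mean[1] + span * s1)
  if (lo >= hi) return(0)
  x <- seq(lo, hi, length.out = n_grid)
  h <- x[2] - x[1]
  cm <- mean[2] + rho * s2 / s1 * (x - mean[1])
  cs <- s2 * sqrt(1 - rho^2)
  inner <- stats::pnorm(upper[2], cm, cs) - stats::pnorm(lower[2], cm, cs)
  sum(simpson_weights(n_grid, h) * stats::dnorm(x, mean[1], s1) * inner)
}

# 3-D analogue: 2-D Simpson grid over (x1, x2), conditional CDF for x3.
oracle_rectangle3 <- function(lower, upper, sigma, mean = c(0, 0, 0),
                              n_grid = 401L, span = 8.5) {
  s11 <- sigma[1:2, 1:2]
  b <- solve(s11, sigma[1:2, 3])
  cvar <- sigma[3, 3] - sum(sigma[1:2, 3] * b)
  sds <- sqrt(diag(sigma))
  grid <- lapply(1:2, function(j) {
    lo <- max(lower[j], mean[j] - span * sds[j])
    hi <- min(upper[j], mean[j] + span * sds[j])
    seq(lo, hi, length.out = n_grid)
  })
  w1 <- simpson_weights(n_grid, grid[[1]][2] - grid[[1]][1])
  w2 <- simpson_weights(n_grid, grid[[2]][2] - grid[[2]][1])
  xy <- as.matrix(expand.grid(x = grid[[1]], y = grid[[2]]))
  dev <- sweep(xy, 2, mean[1:2])
  dens <- mvtnorm::dmvnorm(xy, mean = mean[1:2], sigma = s11)
  cm <- mean[3] + dev %*% b
  inner <- stats::pnorm(upper[3], cm, sqrt(cvar)) -
    stats::pnorm(lower[3], cm, sqrt(cvar))
  sum(as.vector(outer(w1, w2)) * dens * inner)
}

# Random symmetric positive-definite matrix with unit-scale diagonal.
random_spd <- function(p, seed) {
  set.seed(seed)
  L <- matrix(stats::rnorm(p * p, sd = 0.4), p, p)
  s <- crossprod(L) + diag(p)
  d <- sqrt(diag(s))
  s / tcrossprod(d)
}

# Small all-continuous bivariate simulation config used across tests.
toy_specs <- function(traits = c("duration", "efficiency")) {
  sp <- psqi_specs()
  sp <- sp[match(traits, sp$trait), ]
  sp$measure[] <- "continuous"
  sp$n_cat[] <- NA_integer_
  sp
}

toy_components <- function(a11 = 0.4, a22 = 0.3, a12 = 0.12,
                           e12 = 0.18, traits = c("duration", "efficiency")) {
  A <- matrix(c(a11, a12, a12, a22), 2, 2, dimnames = list(traits, traits))
  E <- diag(c(1 - a11, 1 - a22))
  E[1, 2] <- E[2, 1] <- e12
  dimnames(E) <- list(traits, traits)
  variance_components(kind = "AE", A = A, E = E)
}

toy_config <- function(seed, n_mz = 400L, n_dz = 400L, ...) {
  gs <- data.frame(zygosity = c("MZf", "DZf"),
                   pairs = c(n_mz, n_dz), complete = c(n_mz, n_dz))
  twin_sim_config(components = toy_components(...), specs = toy_specs(),
                  thresholds = list(), skew_traits = character(0),
                  group_sizes = gs, seed = seed)
}

# Restrict a twin_dataset to a single trait (keeps ids and covariates).
subset_dataset_trait <- function(d, trait) {
  cols <- c("family_id", "zygosity", "age", "sex1", "sex2",
            paste0(trait, c("_1", "_2")))
  twin_dataset(d$data[, cols], d$specs[d$specs$trait == trait, ])
}
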