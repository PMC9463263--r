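#' Simulation configuration for a synthetic twin cohort
#'
#' Defines the data-generating conditions of the synthetic cohort: the
#' group sizes of the study design, the true variance components on the
#' liability scale, liability thresholds for the ordinal components,
#' age/sex covariate slopes, skew emulation and missingness.
#'
#' Defaults reproduce the reference cohort: 1178 families in five zygosity
#' groups (158 MZ-male pairs of which 120 complete, 197/171 DZ-male,
#' 213/194 MZ-female, 218/187 DZ-female, 392/279 DZ-opposite-sex), age
#' drawn from a normal distribution with mean 53.7, SD 7.3 truncated to
#' 43-71 years, and the published multivariate AE estimates as true
#' variance components. Covariate slopes default to zero (no published
#' effect sizes exist; zero is the neutral choice and the slopes are fully
#' configurable).
#'
#' @param components True [variance_components()] on the liability scale
#'   (default [psqi_reference_components()]).
#' @param specs Measurement specification (default [psqi_specs()]); ordinal
#'   traits are thresholded, continuous traits observed directly.
#' @param group_sizes Data frame with columns `zygosity`, `pairs`,
#'   `complete`.
#' @param thresholds Named list of strictly increasing liability threshold
#'   vectors for each ordinal trait. Defaults emulate typical adult PSQI
#'   category frequencies (most respondents in the low categories, heavy
#'   zero-inflation for medication use).
#' @param beta_age,beta_sex Per-trait covariate slopes on the (rescaled)
#'   age and on sex (0 = female, 1 = male); named vectors, default all 0.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param skew_traits Continuous traits whose liabilities are exponentiated
#'   (then rescaled by the lognormal SD) to emulate right skew, so the
#'   analyst-facing log+1 transform has real work to do. Default: sleep
#'   latency and sleep disturbances.
#' @param missing_rate Extra fraction of complete pairs whose second twin is
#'   masked at random, on top of the per-group incomplete counts.
#' @param seed Integer seed; the generated dataset is a pure function of
#'   the configuration including this seed.
#' @return Object of class `twin_sim_config`.
#' @export
twin_sim_config <- function(components = psqi_reference_components(),
                            specs = psqi_specs(),
                            group_sizes = reference_group_sizes(),
                            thresholds = default_thresholds(specs),
                            beta_age = NULL, beta_sex = NULL,
                            age_mean = 53.7, age_sd = 7.3,
                            age_range = c(43, 71),
                            skew_traits = intersect(c("latency", "disturbances"),
                                                    specs$trait),
                            missing_rate = 0, seed = 1L) {
  stopifnot(inherits(components, "variance_components"))
  if (!identical(components$traits, specs$trait))
    stop_input("components traits must match specs traits")
  if (any(group_sizes$pairs < 0) || any(group_sizes$complete < 0) ||
      any(group_sizes$complete > group_sizes$pairs))
    stop_input("group sizes must satisfy 0 <= complete <= pairs")
  sig <- total_covariance(components)
  if (min_eigval(sig) < -1e-8)
    stop_input("requested total covariance (A + C/D + E) is not positive semidefinite")
  ord <- specs$trait[specs$measure == "ordinal"]
  miss_thr <- setdiff(ord, names(thresholds))
  if (length(miss_thr))
    stop_input("thresholds missing for ordinal traits: %s",
               paste(miss_thr, collapse = ", "))
  for (tr in ord) {
    tau <- thresholds[[tr]]
    if (is.unsorted(tau, strictly = TRUE))
      stop_input("thresholds for '%s' must be strictly increasing", tr)
  }
  zero <- stats::setNames(rep(0, nrow(specs)), specs$trait)
  ba <- zero; bs <- zero
  if (!is.null(beta_age)) ba[names(beta_age)] <- beta_age
  if (!is.null(beta_sex)) bs[names(beta_sex)] <- beta_sex
  structure(list(components = components, specs = specs,
                 group_sizes = group_sizes, thresholds = thresholds,
                 beta_age = ba, beta_sex = bs,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 skew_traits = skew_traits, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "twin_sim_config")
}

#' Zygosity group sizes of the reference cohort
#'
#' @return Data frame with the five groups' total and complete pair counts
#'   (1178 families, 2129 individuals).
#' @export
reference_group_sizes <- function() {
  data.frame(zygosity = zygosity_groups(),
             pairs    = c(158L, 197L, 213L, 218L, 392L),
             complete = c(120L, 171L, 194L, 187L, 279L),
             stringsAsFactors = FALSE)
}

#' Default liability thresholds for the ordinal PSQI components
#'
#' Chosen to emulate typical middle-aged adult category frequencies:
#' subjective quality concentrated in the middle categories, medication use
#' heavily zero-inflated, daytime dysfunction mostly low.
#'
#' @param specs Measurement specification.
#' @return Named list of threshold vectors (length `n_cat - 1`).
#' @export
default_thresholds <- function(specs = psqi_specs()) {
  defaults <- list(
    quality    = stats::qnorm(c(0.20, 0.80, 0.95)),
    medication = stats::qnorm(c(0.75, 0.82, 0.88)),
    daytime    = stats::qnorm(c(0.55, 0.90, 0.98))
  )
  ord <- specs$trait[specs$measure == "ordinal"]
  out <- defaults[intersect(names(defaults), ord)]
  for (tr in setdiff(ord, names(out))) {
    k <- specs$n_cat[specs$trait == tr]
    out[[tr]] <- stats::qnorm(seq_len(k - 1L) / k)
  }
  out
}

#' Generate a synthetic twin cohort with known biometric structure
#'
#' For each pair, the 2p liability vector is drawn from the expected twin
#' covariance of the true components: additive-genetic deviates correlate
#' 1 across MZ and 0.5 across DZ co-twins, shared-environment deviates 1,
#' dominance deviates 1 (MZ) / 0.25 (DZ), and non-shared deviates are
#' independent. Age and sex effects shift the (liability) means; ordinal
#' traits are thresholded into categories; designated skew traits are
#' exponentiated; incomplete pairs are produced by masking twin 2.
#'
#' @param config A [twin_sim_config()].
#' @return A [twin_dataset()] with attributes `seed` and `config`.
#' @export
simulate_twins <- function(config) {
  stopifnot(inherits(config, "twin_sim_config"))
  set.seed(config$seed)
  vc <- config$components
  p <- vc$p
  traits <- vc$traits
  chol_by_class <- list(MZ = chol(expected_twin_covariance(vc, "MZ")),
                        DZ = chol(expected_twin_covariance(vc, "DZ")))
  gs <- config$group_sizes
  n_tot <- sum(gs$pairs)
  zyg <- rep(gs$zygosity, gs$pairs)
  complete <- unlist(lapply(seq_len(nrow(gs)), function(i) {
    c(rep(TRUE, gs$complete[i]), rep(FALSE, gs$pairs[i] - gs$complete[i]))
  }))

  # age: truncated normal via inverse CDF
  lo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  hi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n_tot, lo, hi), config$age_mean, config$age_sd)
  age_scaled <- (age - config$age_range[1]) / diff(config$age_range)

  sex1 <- ifelse(zyg %in% c("MZm", "DZm"), 1,
                 ifelse(zyg %in% c("MZf", "DZf"), 0, NA))
  swap <- stats::runif(n_tot) < 0.5
  sex1[zyg == "DOS"] <- ifelse(swap[zyg == "DOS"], 0, 1)
  sex2 <- ifelse(zyg == "DOS", 1 - sex1, sex1)

  z <- matrix(stats::rnorm(n_tot * 2L * p), n_tot, 2L * p)
  liab <- matrix(NA_real_, n_tot, 2L * p)
  for (cl in c("MZ", "DZ")) {
    idx <- relatedness_class(zyg) == cl
    liab[idx, ] <- z[idx, , drop = FALSE] %*% chol_by_class[[cl]]
  }
  # covariate mean shifts (same slopes for both twins, own sex each)
  for (i in seq_len(p)) {
    liab[, i]     <- liab[, i]     + config$beta_age[i] * age_scaled +
      config$beta_sex[i] * sex1
    liab[, p + i] <- liab[, p + i] + config$beta_age[i] * age_scaled +
      config$beta_sex[i] * sex2
  }

  obs <- liab
  for (tr in config$skew_traits) {
    i <- match(tr, traits)
    v <- diag(total_covariance(vc))[i]
    sdln <- sqrt((exp(v) - 1) * exp(v))  # lognormal SD at this liability variance
    obs[, c(i, p + i)] <- exp(liab[, c(i, p + i)]) / sdln
  }
  for (tr in traits[config$specs$measure == "ordinal"]) {
    i <- match(tr, traits)
    tau <- config$thresholds[[tr]]
    for (col in c(i, p + i))
      obs[, col] <- findInterval(liab[, col], tau)
  }

  df <- data.frame(family_id = sprintf("fam%04d", seq_len(n_tot)),
                   zygosity = zyg, age = age, sex1 = sex1, sex2 = sex2,
                   stringsAsFactors = FALSE)
  for (i in seq_len(p)) {
    df[[paste0(traits[i], "_1")]] <- obs[, i]
    df[[paste0(traits[i], "_2")]] <- obs[, p + i]
  }
  mask2 <- !complete
  if (config$missing_rate > 0)
    mask2 <- mask2 | (stats::runif(n_tot) < config$missing_rate)
  for (i in seq_len(p)) df[mask2, paste0(traits[i], "_2")] <- NA_real_

  out <- twin_dataset(df, config$specs)
  attr(out, "seed") <- config$seed
  attr(out, "config") <- config
  out
}

#' Polychoric correlation by two-step maximum likelihood
#'
#' Thresholds are estimated from the marginal category frequencies
#' (inverse-normal of the cumulative proportions), then the correlation by
#' one-dimensional maximization of the bivariate-normal cell likelihood.
#'
#' @param x,y Integer category vectors (0-based or any coded levels).
#' @param levels_x,levels_y Optional full category sets (so empty extreme
#'   categories keep their place).
#' @return List with `rho`, `tau_x`, `tau_y`, `loglik`.
#' @export
polychoric_correlation <- function(x, y, levels_x = NULL, levels_y = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L) stop_input("too few complete observations for a polychoric estimate")
  lx <- levels_x %||% sort(unique(x))
  ly <- levels_y %||% sort(unique(y))
  tab <- table(factor(x, levels = lx), factor(y, levels = ly))
  margin_tau <- function(counts) {
    cum <- cumsum(counts) / sum(counts)
    stats::qnorm(pmin(pmax(cum[-length(cum)], 1e-6), 1 - 1e-6))
  }
  tau_x <- margin_tau(rowSums(tab))
  tau_y <- margin_tau(colSums(tab))
  bx <- c(-Inf, tau_x, Inf)
  by <- c(-Inf, tau_y, Inf)
  nll <- function(rho) {
    s <- matrix(c(1, rho, rho, 1), 2)
    ll <- 0
    for (i in seq_along(lx)) for (j in seq_along(ly)) {
      n_ij <- tab[i, j]
      if (n_ij == 0L) next
      pr <- mvn_rectangle(lower = c(bx[i], by[j]), upper = c(bx[i + 1L], by[j + 1L]),
                          sigma = s)
      ll <- ll + n_ij * log(max(pr, 1e-300))
    }
    -ll
  }
  opt <- stats::optimize(nll, interval = c(-0.999, 0.999), tol = 1e-7)
  list(rho = opt$minimum, tau_x = tau_x, tau_y = tau_y, loglik = -opt$objective)
}

#' Cross-twin correlations per zygosity class
#'
#' Descriptive twin resemblance: for each trait, the correlation between
#' co-twins among MZ and among DZ pairs, with double entry of twin order.
#' Continuous traits use the product-moment correlation; ordinal traits the
#' polychoric estimate on the double-entered contingency table. DZ same-sex
#' and opposite-sex groups are pooled by default (set `pool_dz = FALSE`
#' for the five separate groups). Pairs with a missing co-twin are
#' excluded. Confidence intervals use the Fisher z approximation with the
#' number of distinct pairs as the effective sample size.
#'
#' @param data A [twin_dataset()].
#' @param pool_dz Pool all DZ groups (default `TRUE`).
#' @param level Confidence level (default 0.95).
#' @return Data frame with one row per trait x zygosity class: `trait`,
#'   `class`, `r`, `lo`, `hi`, `n_pairs`, `method`.
#' @export
cross_twin_correlations <- function(data, pool_dz = TRUE, level = 0.95) {
  stopifnot(inherits(data, "twin_dataset"))
  df <- data$data
  classes <- if (pool_dz) {
    list(MZ = c("MZm", "MZf"), DZ = c("DZm", "DZf", "DOS"))
  } else {
    stats::setNames(as.list(zygosity_groups()), zygosity_groups())
  }
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (cl in names(classes)) {
    sub <- df[df$zygosity %in% classes[[cl]], , drop = FALSE]
    for (k in seq_len(nrow(data$specs))) {
      tr <- data$specs$trait[k]
      v1 <- sub[[paste0(tr, "_1")]]
      v2 <- sub[[paste0(tr, "_2")]]
      ok <- !is.na(v1) & !is.na(v2)
      n <- sum(ok)
      if (n < 3L)
        stop_input("fewer than 3 complete pairs for trait '%s' in class '%s'", tr, cl)
      if (data$specs$measure[k] == "continuous") {
        r <- stats::cor(c(v1[ok], v2[ok]), c(v2[ok], v1[ok]))
        method <- "pearson"
      } else {
        lev <- 0:(data$specs$n_cat[k] - 1L)
        r <- polychoric_correlation(c(v1[ok], v2[ok]), c(v2[ok], v1[ok]),
                                    levels_x = lev, levels_y = lev)$rho
        method <- "polychoric"
      }
      z <- atanh(min(max(r, -0.9999), 0.9999))
      se <- 1 / sqrt(max(n - 3L, 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, class = cl, r = r,
        lo = tanh(z - zcrit * se), hi = tanh(z + zcrit * se),
        n_pairs = n, method = method, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Falconer screening estimates from cross-twin correlations
#'
#' The moment arithmetic behind ACE-vs-ADE model screening:
#' `a2 = 2 (rMZ - rDZ)`, `c2 = 2 rDZ - rMZ`, `e2 = 1 - rMZ`. An ACE model
#' is indicated when the DZ correlation exceeds half the MZ correlation
#' (positive apparent C), an ADE model when it falls below half (apparent
#' dominance). Out-of-band estimates are returned as computed with a
#' warning flag, never clipped.
#'
#' @param rmz,rdz MZ and DZ cross-twin correlations in `[-1, 1]`.
#' @return List with `a2`, `c2`, `e2`, `recommendation` (`"ACE"`, `"ADE"`
#'   or `"boundary"`), and `out_of_band` flag.
#' @export
falconer_estimates <- function(rmz, rdz) {
  if (abs(rmz) > 1 || abs(rdz) > 1)
    stop_input("correlations must lie in [-1, 1]")
  a2 <- 2 * (rmz - rdz)
  c2 <- 2 * rdz - rmz
  e2 <- 1 - rmz
  rec <- if (isTRUE(all.equal(rdz, rmz / 2))) "boundary"
         else if (rdz > rmz / 2) "ACE" else "ADE"
  list(a2 = a2, c2 = c2, e2 = e2, recommendation = rec,
       out_of_band = any(c(a2, c2, e2) < 0 | c(a2, c2, e2) > 1))
}
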