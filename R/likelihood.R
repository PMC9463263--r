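#' Multivariate-normal rectangle probability
#'
#' Deterministic probability that a MVN vector falls in a hyper-rectangle.
#' Dimension 1 uses the normal CDF; dimensions 2-4 the Miwa algorithm with
#' a fixed grid (fully deterministic); higher dimensions the Genz-Bretz
#' quasi-Monte-Carlo rule with a fixed internal seed and tolerance 1e-6, so
#' repeated evaluation of the same rectangle is bit-reproducible (required
#' for a reproducible -2 log-likelihood).
#'
#' @param lower,upper Bound vectors (may be infinite).
#' @param sigma Covariance matrix.
#' @param mean Mean vector (default 0).
#' @return Scalar probability.
#' @export
mvn_rectangle <- function(lower, upper, sigma, mean = rep(0, length(lower))) {
  d <- length(lower)
  if (d == 1L) {
    s <- sqrt(as.numeric(sigma))
    return(stats::pnorm(upper, mean, s) - stats::pnorm(lower, mean, s))
  }
  # finite bounds at +/- 40 SD are probability-identical and keep the Miwa
  # rule quiet about infinite limits
  sd40 <- 40 * sqrt(diag(as.matrix(sigma)))
  lower <- pmax(lower, mean - sd40)
  upper <- pmin(upper, mean + sd40)
  alg <- if (d <= 4L) mvtnorm::Miwa(steps = 128L)
         else mvtnorm::GenzBretz(abseps = 1e-6, maxpts = 50000L)
  val <- tryCatch(
    mvtnorm::pmvnorm(lower = lower, upper = upper, mean = mean,
                     sigma = sigma, algorithm = alg, seed = 42L),
    error = function(e) NA_real_)
  if (is.na(val)) {  # near-singular sigma: retry with a small ridge
    val <- mvtnorm::pmvnorm(lower = lower, upper = upper, mean = mean,
                            sigma = sigma + diag(1e-8, d),
                            algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                           maxpts = 50000L),
                            seed = 42L)
  }
  min(max(as.numeric(val), 0), 1)
}

#' Mean and threshold structure of a twin model
#'
#' Continuous traits have a free intercept plus linear age and sex effects;
#' ordinal traits have liability mean fixed at 0 (identification), age/sex
#' shifting the liability mean, and strictly increasing free thresholds.
#' Age enters rescaled to `[0, 1]` via `age_transform = c(min, span)`.
#'
#' @param traits Trait names.
#' @param intercepts Named vector of intercepts for continuous traits
#'   (ordinal entries must be 0; default all 0).
#' @param beta_age,beta_sex Named per-trait covariate slopes (default 0).
#' @param thresholds Named list of strictly increasing threshold vectors
#'   for the ordinal traits.
#' @param age_transform `c(min, span)`; scaled age is `(age - min)/span`.
#'   Default `c(0, 1)` (age used as supplied).
#' @return Object of class `mean_threshold_model`.
#' @export
mean_threshold_model <- function(traits, intercepts = NULL, beta_age = NULL,
                                 beta_sex = NULL, thresholds = list(),
                                 age_transform = c(0, 1)) {
  zero <- stats::setNames(rep(0, length(traits)), traits)
  fill <- function(x) { z <- zero; if (!is.null(x)) z[names(x)] <- x; z }
  for (tr in names(thresholds))
    if (is.unsorted(thresholds[[tr]], strictly = TRUE))
      stop_input("thresholds for '%s' must be strictly increasing", tr)
  structure(list(traits = traits, intercepts = fill(intercepts),
                 beta_age = fill(beta_age), beta_sex = fill(beta_sex),
                 thresholds = thresholds, age_transform = age_transform),
            class = "mean_threshold_model")
}

# liability/trait means for one pair: 2p vector (twin1 traits, twin2 traits)
pair_means <- function(mt, age, sex1, sex2) {
  a <- (age - mt$age_transform[1]) / mt$age_transform[2]
  m1 <- mt$intercepts + mt$beta_age * a + mt$beta_sex * sex1
  m2 <- mt$intercepts + mt$beta_age * a + mt$beta_sex * sex2
  c(m1, m2)
}

#' Log-likelihood contribution of one twin-pair record
#'
#' Full-information likelihood for a pair mixing continuous and ordinal
#' traits. The observed continuous sub-vector contributes a multivariate
#' normal log-density at its covariate-adjusted mean; the ordinal
#' sub-vector contributes the log probability of the rectangle between its
#' thresholds under the normal liability distribution conditioned
#' analytically on the observed continuous values (reducing the
#' integration dimension). A missing co-twin marginalizes to the singleton
#' likelihood; arbitrary within-twin missingness is likewise marginalized.
#'
#' @param record One-row wide data frame (see [twin_dataset()]).
#' @param vc [variance_components()].
#' @param mt [mean_threshold_model()].
#' @param specs Measurement specification (default [psqi_specs()] subset to
#'   `vc$traits`).
#' @return Scalar log-likelihood (0 for a fully missing record).
#' @export
pair_loglik <- function(record, vc, mt, specs = NULL) {
  specs <- specs %||% psqi_specs()[match(vc$traits, psqi_specs()$trait), ]
  p <- vc$p
  sigma <- expected_twin_covariance(vc, as.character(record$zygosity))
  y <- as.numeric(c(record[paste0(vc$traits, "_1")],
                    record[paste0(vc$traits, "_2")]))
  mu <- pair_means(mt, record$age, record$sex1, record$sex2)
  measure2 <- rep(specs$measure, 2L)
  trait2 <- rep(vc$traits, 2L)
  obs <- which(!is.na(y))
  if (!length(obs)) return(0)
  loglik_obs(y, mu, sigma, obs, measure2, trait2, mt$thresholds)
}

# core likelihood for an observed index subset of the stacked 2p vector
loglik_obs <- function(y, mu, sigma, obs, measure2, trait2, thresholds) {
  cidx <- obs[measure2[obs] == "continuous"]
  oidx <- obs[measure2[obs] == "ordinal"]
  ll <- 0
  if (length(cidx)) {
    s_cc <- sigma[cidx, cidx, drop = FALSE]
    cs <- chol_safe(s_cc)
    if (is.null(cs)) return(-1e10)
    r <- y[cidx] - mu[cidx]
    ll <- ll - 0.5 * (length(cidx) * log(2 * pi) + cs$logdet +
                        sum(r * (cs$inv %*% r)))
  }
  if (length(oidx)) {
    if (length(cidx)) {
      s_oc <- sigma[oidx, cidx, drop = FALSE]
      cs <- chol_safe(sigma[cidx, cidx, drop = FALSE])
      if (is.null(cs)) return(-1e10)
      B <- s_oc %*% cs$inv
      cmean <- mu[oidx] + as.numeric(B %*% (y[cidx] - mu[cidx]))
      ccov <- sigma[oidx, oidx, drop = FALSE] - B %*% t(s_oc)
      ccov <- (ccov + t(ccov)) / 2
    } else {
      cmean <- mu[oidx]
      ccov <- sigma[oidx, oidx, drop = FALSE]
    }
    lo <- hi <- numeric(length(oidx))
    for (k in seq_along(oidx)) {
      tau <- c(-Inf, thresholds[[trait2[oidx[k]]]], Inf)
      cat_k <- y[oidx[k]]
      lo[k] <- tau[cat_k + 1L]
      hi[k] <- tau[cat_k + 2L]
    }
    pr <- mvn_rectangle(lo, hi, sigma = ccov, mean = cmean)
    ll <- ll + log(max(pr, 1e-300))
  }
  ll
}

# ---------------------------------------------------------------------------
# dataset preparation for fitting

prep_likelihood <- function(model, data) {
  stopifnot(inherits(data, "twin_dataset"))
  if (!identical(model$traits, data$specs$trait[match(model$traits,
                                                      data$specs$trait)]))
    stop_input("model traits not all present in dataset")
  specs <- data$specs[match(model$traits, data$specs$trait), ]
  if (!identical(specs$measure, model$specs$measure))
    stop_input("model/data measurement kinds disagree")
  df <- data$data
  p <- length(model$traits)
  cols1 <- paste0(model$traits, "_1")
  cols2 <- paste0(model$traits, "_2")
  Y <- as.matrix(df[, c(cols1, cols2)])
  cls <- relatedness_class(df$zygosity)
  age_min <- min(df$age); age_span <- max(diff(range(df$age)), 1e-12)
  keep <- rowSums(!is.na(Y)) > 0
  all_cont <- all(specs$measure == "continuous")
  measure2 <- rep(specs$measure, 2L)
  trait2 <- rep(model$traits, 2L)

  groups <- list()
  if (all_cont) {
    pat <- apply(!is.na(Y), 1L, paste, collapse = "")
    key <- paste(cls, pat)
    for (k in unique(key[keep])) {
      idx <- which(key == k & keep)
      obs <- which(!is.na(Y[idx[1L], ]))
      groups[[k]] <- list(class = cls[idx[1L]], obs = obs,
                          Y = Y[idx, obs, drop = FALSE],
                          age = df$age[idx], sex1 = df$sex1[idx],
                          sex2 = df$sex2[idx], n = length(idx))
    }
  }
  list(specs = specs, p = p, Y = Y, cls = cls, df = df, keep = keep,
       n_pairs = sum(keep), all_cont = all_cont, groups = groups,
       measure2 = measure2, trait2 = trait2,
       age_transform = c(age_min, age_span))
}

# -2LL over the dataset, continuous fast path (vectorized by pattern group)
neg2ll_continuous <- function(vc, mt, prep) {
  sig <- list(MZ = expected_twin_covariance(vc, "MZ"),
              DZ = expected_twin_covariance(vc, "DZ"))
  tot <- 0
  for (g in prep$groups) {
    s <- sig[[g$class]][g$obs, g$obs, drop = FALSE]
    cs <- chol_safe(s)
    if (is.null(cs)) return(Inf)
    M <- group_means(mt, g, prep$p)
    R <- g$Y - M
    tot <- tot + g$n * (ncol(R) * log(2 * pi) + cs$logdet) +
      sum((R %*% cs$inv) * R)
  }
  tot
}

group_means <- function(mt, g, p) {
  a <- (g$age - mt$age_transform[1]) / mt$age_transform[2]
  M <- matrix(0, g$n, length(g$obs))
  for (j in seq_along(g$obs)) {
    u <- g$obs[j]
    i <- if (u <= p) u else u - p
    sx <- if (u <= p) g$sex1 else g$sex2
    M[, j] <- mt$intercepts[i] + mt$beta_age[i] * a + mt$beta_sex[i] * sx
  }
  M
}

# -2LL, general mixed path (per pair; pools identical all-ordinal patterns
# when the model carries no covariates)
neg2ll_mixed <- function(vc, mt, prep) {
  sig <- list(MZ = expected_twin_covariance(vc, "MZ"),
              DZ = expected_twin_covariance(vc, "DZ"))
  if (is.null(chol_safe(sig$MZ)) || is.null(chol_safe(sig$DZ))) return(Inf)
  p <- prep$p
  df <- prep$df
  no_cov <- all(mt$beta_age == 0) && all(mt$beta_sex == 0)
  poolable <- no_cov & apply(prep$Y, 1L, function(r) {
    obs <- !is.na(r)
    any(obs) && all(prep$measure2[obs] == "ordinal")
  })
  ll <- 0
  if (any(poolable & prep$keep)) {
    idx <- which(poolable & prep$keep)
    key <- paste(prep$cls[idx], apply(prep$Y[idx, , drop = FALSE], 1L,
                                      paste, collapse = ","))
    for (k in unique(key)) {
      sub <- idx[key == k]
      i1 <- sub[1L]
      mu <- pair_means(mt, df$age[i1], df$sex1[i1], df$sex2[i1])
      obs <- which(!is.na(prep$Y[i1, ]))
      l1 <- loglik_obs(prep$Y[i1, ], mu, sig[[prep$cls[i1]]], obs,
                       prep$measure2, prep$trait2, mt$thresholds)
      ll <- ll + length(sub) * l1
    }
  }
  rest <- which(prep$keep & !poolable)
  for (i in rest) {
    mu <- pair_means(mt, df$age[i], df$sex1[i], df$sex2[i])
    obs <- which(!is.na(prep$Y[i, ]))
    ll <- ll + loglik_obs(prep$Y[i, ], mu, sig[[prep$cls[i]]], obs,
                          prep$measure2, prep$trait2, mt$thresholds)
  }
  -2 * ll
}

# objective closure; returns penalty values (finite, optimizer-safe) when
# the implied total covariance leaves the PD cone
make_objective <- function(model, prep) {
  function(par) {
    um <- tryCatch(model$unpack(par, prep$age_transform),
                   error = function(e) NULL)
    if (is.null(um)) return(1e10)
    if (!is.null(um$penalty) && um$penalty > 0)
      return(1e9 * (1 + um$penalty))
    me <- min_eigval(total_covariance(um$vc))
    if (me < 1e-10) return(1e9 * (1 - me))
    val <- if (prep$all_cont) neg2ll_continuous(um$vc, um$mt, prep)
           else neg2ll_mixed(um$vc, um$mt, prep)
    if (!is.finite(val)) return(1e9)
    val
  }
}

# analytic gradient for the direct-symmetric multivariate model on
# all-continuous data; falls back to finite differences in penalty regions
make_gradient <- function(model, prep, fn) {
  if (model$type != "multivariate" || !prep$all_cont) return(NULL)
  p <- prep$p
  pr <- vech_pairs(p)
  function(par) {
    um <- tryCatch(model$unpack(par, prep$age_transform),
                   error = function(e) NULL)
    feasible <- !is.null(um) && (is.null(um$penalty) || um$penalty <= 0) &&
      min_eigval(total_covariance(um$vc)) >= 1e-10
    if (!feasible) return(fd_gradient(fn, par))
    vc <- um$vc; mt <- um$mt
    sig <- list(MZ = expected_twin_covariance(vc, "MZ"),
                DZ = expected_twin_covariance(vc, "DZ"))
    kapA <- c(MZ = 1, DZ = 0.5)
    kapC <- switch(vc$kind, ADE = c(MZ = 1, DZ = 0.25), c(MZ = 1, DZ = 1))
    GA <- GC <- GE <- matrix(0, p, p)
    gmu <- gba <- gbs <- rep(0, p)
    for (g in prep$groups) {
      s <- sig[[g$class]][g$obs, g$obs, drop = FALSE]
      cs <- chol_safe(s)
      if (is.null(cs)) return(fd_gradient(fn, par))
      M <- group_means(mt, g, p)
      R <- g$Y - M
      P <- cs$inv
      Q <- R %*% P
      W <- matrix(0, 2 * p, 2 * p)
      W[g$obs, g$obs] <- g$n * P - crossprod(Q)   # t(Q) %*% R symmetrized below
      # note crossprod(Q) = P R'R P since P symmetric
      W11 <- W[1:p, 1:p]; W22 <- W[p + 1:p, p + 1:p]
      W12 <- W[1:p, p + 1:p]; W21 <- W[p + 1:p, 1:p]
      within <- W11 + W22
      cross <- W12 + W21
      GE <- GE + within
      if (vc$kind %in% c("ACE", "ADE", "AE"))
        GA <- GA + within + kapA[[g$class]] * cross
      if (vc$kind %in% c("ACE", "ADE", "CE"))
        GC <- GC + within + kapC[[g$class]] * cross
      # mean gradients: d(-2LL)/dM = -2 Q
      a <- (g$age - mt$age_transform[1]) / mt$age_transform[2]
      for (j in seq_along(g$obs)) {
        u <- g$obs[j]
        i <- if (u <= p) u else u - p
        sx <- if (u <= p) g$sex1 else g$sex2
        gmu[i] <- gmu[i] - 2 * sum(Q[, j])
        gba[i] <- gba[i] - 2 * sum(Q[, j] * a)
        gbs[i] <- gbs[i] - 2 * sum(Q[, j] * sx)
      }
    }
    tovech <- function(G) {
      v <- numeric(nrow(pr))
      for (k in seq_len(nrow(pr))) {
        i <- pr[k, 1L]; j <- pr[k, 2L]
        v[k] <- if (i == j) G[i, i] else G[i, j] + G[j, i]
      }
      v
    }
    out <- c(if (vc$kind %in% c("ACE", "ADE", "AE")) tovech(GA),
             if (vc$kind %in% c("ACE", "ADE", "CE")) tovech(GC),
             tovech(GE),
             gmu,
             if (model$covariates) c(gba, gbs))
    names(out) <- model$par_names
    out
  }
}

fd_gradient <- function(fn, par, h = 1e-6) {
  f0 <- fn(par)
  vapply(seq_along(par), function(k) {
    ph <- par; ph[k] <- ph[k] + h
    (fn(ph) - f0) / h
  }, numeric(1))
}

#' Fit a twin model by full-information maximum likelihood
#'
#' Minimizes the summed pair -2 log-likelihoods with a quasi-Newton
#' optimizer (PORT routines via [stats::nlminb()]) under the model's box
#' constraints, starting from moment-based values with optional jittered
#' restarts. Continuous-only data use a vectorized likelihood with analytic
#' gradient; data with ordinal traits use the conditioned
#' rectangle-probability likelihood.
#'
#' @param model A model specification from [build_multivariate()],
#'   [build_common_pathway()] or [build_independent_pathway()].
#' @param data A [twin_dataset()].
#' @param restarts Number of jittered restarts after the moment start
#'   (default 5; the best solution is kept).
#' @param seed Seed controlling restart jitter.
#' @param start Optional explicit start vector (overrides the moment start).
#' @param control Passed to [stats::nlminb()]; defaults set
#'   `rel.tol = 1e-10` and generous evaluation limits.
#' @return Object of class `twin_fit`: named `estimates`, `minus2LL`,
#'   `n_params`, `AIC = minus2LL + 2 n_params`, `converged`,
#'   `n_pairs_used`, the implied [variance_components()] (`vc`) and
#'   [mean_threshold_model()] (`mt`), and optimizer metadata.
#' @export
fit_twin_model <- function(model, data, restarts = 5L, seed = 1L,
                           start = NULL, control = list()) {
  stopifnot(inherits(model, "twin_model"))
  prep <- prep_likelihood(model, data)
  if (prep$n_pairs < 1L) stop_input("no usable pairs in dataset")
  fn <- make_objective(model, prep)
  gr <- make_gradient(model, prep, fn)
  ctl <- utils::modifyList(list(rel.tol = 1e-10, eval.max = 5000L,
                                iter.max = 2000L), control)
  s0 <- start %||% model$start(prep)
  run <- function(par0) {
    stats::nlminb(par0, fn, gradient = gr, lower = model$lower,
                  upper = model$upper, control = ctl)
  }
  best <- run(s0)
  if (restarts > 0L) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      par0 <- s0 + stats::rnorm(length(s0), 0, 0.05 * (abs(s0) + 0.1))
      par0 <- pmin(pmax(par0, model$lower + 1e-6), model$upper - 1e-6)
      cand <- tryCatch(run(par0), error = function(e) NULL)
      if (!is.null(cand) && is.finite(cand$objective) &&
          cand$objective < best$objective - 1e-9) best <- cand
    }
  }
  conv <- best$convergence == 0 && best$objective < 1e8
  if (!conv && best$objective >= 1e8)
    warning("optimizer did not reach a feasible solution; best point returned")
  um <- model$unpack(best$par, prep$age_transform)
  est <- stats::setNames(best$par, model$par_names)
  n_par <- length(best$par)
  structure(list(estimates = est, minus2LL = best$objective,
                 n_params = n_par, AIC = best$objective + 2 * n_par,
                 converged = conv, n_pairs_used = prep$n_pairs,
                 vc = um$vc, mt = um$mt, model = model,
                 optim = list(message = best$message,
                              iterations = best$iterations),
                 age_transform = prep$age_transform),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("<twin_fit> %s %s: -2LL = %.3f, k = %d, AIC = %.3f, %s\n",
              x$model$type, x$model$kind, x$minus2LL, x$n_params, x$AIC,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  %d pairs used\n", x$n_pairs_used))
  invisible(x)
}

#' Likelihood-ratio and AIC comparison of two nested fits
#'
#' @param full Fit of the richer model.
#' @param nested Fit of the restricted model (fewer parameters, same data).
#' @param tol Tolerance for a negative chi-square before declaring an
#'   optimizer artifact (default 0.01).
#' @return List with `chi2`, `df`, `p` (chi-square upper tail) and
#'   `deltaAIC = nested$AIC - full$AIC`.
#' @export
compare_fits <- function(full, nested, tol = 0.01) {
  stopifnot(inherits(full, "twin_fit"), inherits(nested, "twin_fit"))
  if (nested$n_params > full$n_params)
    stop_input("nested model must not have more parameters than the full model")
  chi2 <- nested$minus2LL - full$minus2LL
  if (chi2 < -tol)
    stop_input("nested -2LL below full -2LL by %.4f: refit needed (optimizer artifact)",
               -chi2)
  chi2 <- max(chi2, 0)
  df <- full$n_params - nested$n_params
  p <- if (df == 0L) as.numeric(chi2 <= tol) else
    stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, deltaAIC = nested$AIC - full$AIC)
}

#' Profile-likelihood confidence interval
#'
#' Bound where the profiled -2 log-likelihood rises by the chi-square(1)
#' quantile of the requested level. `what` may be a free parameter name or
#' a function `g(par)` of the parameter vector (a derived quantity such as
#' a standardized h2); the constraint `g(par) = c` is enforced during the
#' inner re-optimization by a quadratic penalty with weight 1e6.
#'
#' @param fit A converged [fit_twin_model()] result.
#' @param data The dataset the fit used.
#' @param what Parameter name or function of the parameter vector.
#' @param level Confidence level (default 0.95).
#' @param bounds Optional hard box for the quantity (e.g. `c(0, 1)` for a
#'   standardized component); a profile that never reaches the cutoff
#'   before the box edge reports the edge with a `boundary` flag.
#' @param step Initial search step (default: 0.25 of the quantity's scale).
#' @return List with `estimate`, `lo`, `hi`, `lo_boundary`, `hi_boundary`.
#' @export
profile_ci <- function(fit, data, what, level = 0.95, bounds = c(-Inf, Inf),
                       step = NULL) {
  stopifnot(inherits(fit, "twin_fit"))
  model <- fit$model
  prep <- prep_likelihood(model, data)
  fn <- make_objective(model, prep)
  g <- if (is.character(what)) {
    k <- match(what, model$par_names)
    if (is.na(k)) stop_input("unknown parameter '%s'", what)
    function(par) par[k]
  } else what
  v0 <- g(fit$estimates)
  base <- fit$minus2LL
  cut <- stats::qchisq(level, 1)
  w <- 1e6
  warm <- fit$estimates
  profiled <- function(cval) {
    obj <- function(par) fn(par) + w * (g(par) - cval)^2
    res <- stats::nlminb(warm, obj, lower = model$lower, upper = model$upper,
                         control = list(rel.tol = 1e-10, eval.max = 3000L))
    warm <<- res$par
    fn(res$par)
  }
  st <- step %||% (0.25 * max(abs(v0), 0.2))
  one_side <- function(dir) {
    warm <<- fit$estimates
    lim <- if (dir > 0) bounds[2] else bounds[1]
    cval <- v0
    for (i in 1:30) {
      nxt <- cval + dir * st * 2^(i - 1)
      hit_lim <- (dir > 0 && nxt >= lim) || (dir < 0 && nxt <= lim)
      if (hit_lim) nxt <- lim
      d <- profiled(nxt) - base - cut
      if (d >= 0) {
        root <- stats::uniroot(function(c) profiled(c) - base - cut,
                               lower = min(cval, nxt), upper = max(cval, nxt),
                               tol = 1e-4)$root
        return(list(bound = root, boundary = FALSE))
      }
      cval <- nxt
      if (hit_lim) return(list(bound = lim, boundary = TRUE))
    }
    list(bound = cval, boundary = TRUE)
  }
  lo <- one_side(-1)
  hi <- one_side(+1)
  list(estimate = v0, lo = lo$bound, hi = hi$bound,
       lo_boundary = lo$boundary, hi_boundary = hi$boundary)
}
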