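# Phenotypic confirmatory factor analysis of the seven components on one
# randomly selected twin per pair, with from-scratch ML fitting and fit
# indices.

#' Select one twin per pair for phenotypic analysis
#'
#' Twin pairs are statistically dependent; phenotypic factor analysis uses
#' one randomly chosen twin from each family. Only complete-case twins
#' (all traits observed) are eligible; a family whose only present twin is
#' incomplete is dropped. Reproducible from the seed.
#'
#' @param data A [twin_dataset()].
#' @param seed Integer seed for the random selection.
#' @return Data frame with `family_id`, `zygosity`, `twin`, `sex`, `age`
#'   and one column per trait.
#' @export
select_one_twin_per_pair <- function(data, seed = 1L) {
  stopifnot(inherits(data, "twin_dataset"))
  df <- data$data
  if (nrow(df) == 0L) stop_input("empty dataset")
  tr <- data$specs$trait
  ok1 <- rowSums(is.na(df[, paste0(tr, "_1"), drop = FALSE])) == 0L
  ok2 <- rowSums(is.na(df[, paste0(tr, "_2"), drop = FALSE])) == 0L
  set.seed(seed)
  pick <- ifelse(ok1 & ok2, ifelse(stats::runif(nrow(df)) < 0.5, 1L, 2L),
                 ifelse(ok1, 1L, ifelse(ok2, 2L, NA_integer_)))
  keep <- which(!is.na(pick))
  out <- data.frame(family_id = df$family_id[keep],
                    zygosity = df$zygosity[keep], twin = pick[keep],
                    sex = ifelse(pick[keep] == 1L, df$sex1[keep], df$sex2[keep]),
                    age = df$age[keep], stringsAsFactors = FALSE)
  for (v in tr)
    out[[v]] <- ifelse(pick[keep] == 1L, df[[paste0(v, "_1")]][keep],
                       df[[paste0(v, "_2")]][keep])
  out
}

#' Specification of a confirmatory factor model
#'
#' @param structure Named list factor -> trait names (each trait on exactly
#'   one factor). Defaults to the single-factor structure over the seven
#'   components.
#' @param residual_pairs List of length-2 character vectors naming trait
#'   pairs given a free residual covariance (e.g. duration-efficiency and
#'   latency-efficiency, whose scores are arithmetically entangled).
#' @param factor_correlations `"free"` (estimated), `"unit"` (fixed at 1,
#'   collapsing the factors into one) or `"zero"` (orthogonal).
#' @return Object of class `cfa_spec`.
#' @export
cfa_spec <- function(structure = list(sleep_quality = psqi_components()),
                     residual_pairs = list(),
                     factor_correlations = c("free", "unit", "zero")) {
  factor_correlations <- match.arg(factor_correlations)
  all_tr <- unlist(structure, use.names = FALSE)
  if (anyDuplicated(all_tr))
    stop_input("each trait must load on exactly one factor; duplicated: %s",
               paste(unique(all_tr[duplicated(all_tr)]), collapse = ", "))
  traits <- all_tr
  for (pr in residual_pairs) {
    if (length(pr) != 2L || pr[1L] == pr[2L])
      stop_input("residual pairs must be two distinct traits")
    if (!all(pr %in% traits))
      stop_input("residual pair names unknown trait(s): %s",
                 paste(setdiff(pr, traits), collapse = ", "))
  }
  if (length(residual_pairs) > 1L) {
    keys <- vapply(residual_pairs, function(x) paste(sort(x), collapse = "|"),
                   character(1))
    if (anyDuplicated(keys)) stop_input("duplicate residual pairs")
  }
  structure(list(structure = structure, residual_pairs = residual_pairs,
                 factor_correlations = factor_correlations),
            class = "cfa_spec")
}

#' The three competing PSQI factor structures
#'
#' Convenience constructors: the original single-factor model, the
#' single-factor model with residual covariances between sleep
#' duration-efficiency and latency-efficiency, and the Cole 3-factor
#' clustering.
#'
#' @return Named list of three [cfa_spec()] objects.
#' @export
psqi_cfa_specs <- function() {
  list(
    one_factor = cfa_spec(),
    one_factor_resid = cfa_spec(residual_pairs = list(
      c("duration", "efficiency"), c("latency", "efficiency"))),
    cole_three_factor = cfa_spec(structure = cole_structure())
  )
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Fits the implied covariance `Sigma = Lambda Phi Lambda' + Psi` (unit
#' factor variances, free loadings, diagonal residual covariance plus any
#' specified residual pairs) to a sample covariance matrix by minimizing
#' the normal-theory ML discrepancy
#' `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`. Components are treated
#' as continuous (Pearson covariance); pass a polychoric matrix as `S` for
#' the categorical variant. The baseline model for the incremental indices
#' is the independence model with free variances.
#'
#' @param spec A [cfa_spec()].
#' @param table Single-respondent data frame (e.g. from
#'   [select_one_twin_per_pair()]) containing the trait columns; or supply
#'   `S` and `n` directly.
#' @param S Optional sample covariance matrix (traits in rownames).
#' @param n Number of observations (required with `S`).
#' @return Object of class `cfa_fit`: `loadings`, `factor_correlations`,
#'   `residual_cov`, `implied`, `residual_correlations`, `indices`
#'   (a [fit_indices()] result), `converged`, `n_obs`, `n_params`.
#' @export
fit_cfa <- function(spec, table = NULL, S = NULL, n = NULL) {
  stopifnot(inherits(spec, "cfa_spec"))
  traits <- unlist(spec$structure, use.names = FALSE)
  if (is.null(S)) {
    if (is.null(table)) stop_input("supply either `table` or `S` and `n`")
    miss <- setdiff(traits, names(table))
    if (length(miss)) stop_input("table lacks trait columns: %s",
                                 paste(miss, collapse = ", "))
    X <- as.matrix(table[, traits, drop = FALSE])
    X <- X[stats::complete.cases(X), , drop = FALSE]
    n <- nrow(X)
    S <- stats::cov(X)
  } else {
    S <- as.matrix(S)[traits, traits]
    if (is.null(n)) stop_input("`n` required with a covariance input")
  }
  p <- length(traits)
  if (n <= p * (p + 1) / 2)
    stop_input("sample size too small for the number of moments")
  if (min_eigval(S) < 1e-10) stop_input("sample covariance is not positive definite")
  L <- assignment_matrix(spec$structure, traits)
  nf <- ncol(L)
  free_phi <- nf > 1L && spec$factor_correlations == "free"
  nphi <- if (free_phi) nf * (nf - 1L) / 2L else 0L
  rp_idx <- lapply(spec$residual_pairs, function(pr) match(pr, traits))
  n_params <- p + nphi + p + length(rp_idx)

  implied <- function(par) {
    off <- 0L
    lam <- par[off + seq_len(p)]; off <- off + p
    Phi <- switch(spec$factor_correlations,
                  free = diag(nf), unit = matrix(1, nf, nf),
                  zero = diag(nf))
    if (free_phi) {
      pf <- vech_pairs(nf)
      od <- which(pf[, 1L] != pf[, 2L])
      v <- par[off + seq_len(nphi)]; off <- off + nphi
      for (k in seq_along(od)) {
        Phi[pf[od[k], 1L], pf[od[k], 2L]] <- v[k]
        Phi[pf[od[k], 2L], pf[od[k], 1L]] <- v[k]
      }
    }
    psi <- par[off + seq_len(p)]; off <- off + p
    Psi <- diag(psi, p)
    for (k in seq_along(rp_idx)) {
      i <- rp_idx[[k]][1L]; j <- rp_idx[[k]][2L]
      Psi[i, j] <- Psi[j, i] <- par[off + k]
    }
    Lam <- L * lam
    Lam %*% Phi %*% t(Lam) + Psi
  }
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  discrepancy <- function(par) {
    Sg <- implied(par)
    cs <- chol_safe(Sg)
    if (is.null(cs)) return(1e8)
    cs$logdet + sum(S * cs$inv) - as.numeric(logdetS) - p
  }
  # starts: principal-component loadings within each factor
  R <- stats::cov2cor(S)
  sds <- sqrt(diag(S))
  lam0 <- numeric(p)
  for (f in seq_len(nf)) {
    trf <- which(L[, f] == 1L)
    if (length(trf) == 1L) { lam0[trf] <- 0.7 * sds[trf]; next }
    ev <- eigen(R[trf, trf], symmetric = TRUE)
    v <- ev$vectors[, 1L]
    if (v[1L] < 0) v <- -v
    lam0[trf] <- pmin(abs(v) * sqrt(ev$values[1L]), 0.95) * sign(v) * sds[trf]
  }
  par0 <- c(lam0, rep(0.3, nphi), pmax(0.5 * diag(S), 1e-3),
            rep(0, length(rp_idx)))
  lower <- c(rep(-Inf, p), rep(-0.99, nphi), rep(1e-6, p),
             rep(-Inf, length(rp_idx)))
  upper <- c(rep(Inf, p), rep(0.99, nphi), rep(Inf, p),
             rep(Inf, length(rp_idx)))
  opt <- stats::nlminb(par0, discrepancy, lower = lower, upper = upper,
                       control = list(rel.tol = 1e-12, eval.max = 5000L))
  if (opt$objective >= 1e7) stop_input("CFA optimization failed to find a PD solution")
  Sg <- implied(opt$par)
  Fmin <- max(opt$objective, 0)
  chi2 <- (n - 1) * Fmin
  df <- p * (p + 1) / 2 - n_params
  # independence baseline with free variances
  Fb <- sum(log(diag(S))) - as.numeric(logdetS)
  chi2_b <- (n - 1) * Fb
  df_b <- p * (p - 1) / 2
  resid_cor <- R - stats::cov2cor(Sg)
  srmr <- sqrt(mean(resid_cor[lower.tri(resid_cor)]^2))
  idx <- fit_indices(chi2 = chi2, df = df, chi2_b = chi2_b, df_b = df_b,
                     n = n, n_params = n_params, srmr = srmr)
  lam_hat <- stats::setNames(opt$par[seq_len(p)], traits)
  Phi_hat <- {
    m <- switch(spec$factor_correlations, free = diag(nf),
                unit = matrix(1, nf, nf), zero = diag(nf))
    if (free_phi) {
      pf <- vech_pairs(nf); od <- which(pf[, 1L] != pf[, 2L])
      v <- opt$par[p + seq_len(nphi)]
      for (k in seq_along(od)) {
        m[pf[od[k], 1L], pf[od[k], 2L]] <- v[k]
        m[pf[od[k], 2L], pf[od[k], 1L]] <- v[k]
      }
    }
    dimnames(m) <- list(names(spec$structure), names(spec$structure))
    m
  }
  structure(list(spec = spec, loadings = lam_hat,
                 factor_correlations = Phi_hat,
                 residual_cov = {
                   psi <- diag(opt$par[p + nphi + seq_len(p)], p)
                   for (k in seq_along(rp_idx)) {
                     i <- rp_idx[[k]][1L]; j <- rp_idx[[k]][2L]
                     psi[i, j] <- psi[j, i] <- opt$par[p + nphi + p + k]
                   }
                   dimnames(psi) <- list(traits, traits)
                   psi
                 },
                 implied = Sg, sample_cov = S,
                 residual_correlations = resid_cor,
                 indices = idx, converged = opt$convergence == 0,
                 n_obs = n, n_params = n_params),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  i <- x$indices
  cat(sprintf("<cfa_fit> %d factors, n = %d, k = %d\n",
              length(x$spec$structure), x$n_obs, x$n_params))
  cat(sprintf("  chi2(%d) = %.2f, RMSEA = %.3f (%.3f, %.3f), SRMR = %.3f\n",
              i$df, i$chi2, i$RMSEA, i$RMSEA_lo, i$RMSEA_hi, i$SRMR))
  cat(sprintf("  CFI = %.3f, TLI = %.3f, BIC = %.2f\n", i$CFI, i$TLI, i$BIC))
  invisible(x)
}

#' Fit indices from chi-square statistics
#'
#' Computes the standard absolute and incremental fit indices from the
#' model and baseline chi-squares:
#' `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))` with a 90% CI by
#' noncentral chi-square inversion;
#' `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`;
#' `TLI = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)`, truncated at
#' 1; `BIC = chi2 + n_params log(n)` (deviance scale: only differences
#' between models on the same data are meaningful). Conventional cutoffs
#' for good fit: CFI/TLI near 0.95, RMSEA near 0.06, SRMR near 0.08.
#'
#' @param chi2,df Model chi-square and degrees of freedom.
#' @param chi2_b,df_b Baseline (independence) chi-square and df.
#' @param n Number of observations.
#' @param n_params Number of free parameters (for BIC).
#' @param srmr Optional externally computed SRMR to carry along.
#' @param ci_level RMSEA confidence level (default 0.90).
#' @return List with `chi2`, `df`, `chi2_baseline`, `df_baseline`, `n_obs`,
#'   `RMSEA`, `RMSEA_lo`, `RMSEA_hi`, `CFI`, `TLI`, `BIC`, `SRMR`.
#' @export
fit_indices <- function(chi2, df, chi2_b, df_b, n, n_params,
                        srmr = NA_real_, ci_level = 0.90) {
  if (df <= 0 || df_b <= 0) stop_input("df and df_b must be positive")
  if (df_b <= df) stop_input("baseline df must exceed model df")
  if (n <= 1) stop_input("n must exceed 1")
  rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  alpha <- (1 - ci_level) / 2
  ncp_bound <- function(target_p) {
    # lambda with P(chisq_df(lambda) <= chi2) = target_p
    f <- function(l) stats::pchisq(chi2, df, ncp = l) - target_p
    if (f(0) < 0) return(0)
    up <- max(chi2 * 2, 10)
    while (f(up) > 0 && up < 1e7) up <- up * 2
    stats::uniroot(f, c(0, up), tol = 1e-8)$root
  }
  lam_lo <- ncp_bound(1 - alpha)
  lam_hi <- ncp_bound(alpha)
  denom <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (denom <= 0) 1 else 1 - max(chi2 - df, 0) / denom
  tli_raw <- ((chi2_b / df_b) - (chi2 / df)) / ((chi2_b / df_b) - 1)
  list(chi2 = chi2, df = df, chi2_baseline = chi2_b, df_baseline = df_b,
       n_obs = n,
       RMSEA = rmsea,
       RMSEA_lo = sqrt(lam_lo / (df * (n - 1))),
       RMSEA_hi = sqrt(lam_hi / (df * (n - 1))),
       CFI = min(max(cfi, 0), 1),
       TLI = min(tli_raw, 1),
       BIC = chi2 + n_params * log(n),
       SRMR = srmr)
}
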