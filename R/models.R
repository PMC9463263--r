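# Model builders: each returns a `twin_model` object carrying the free
# parameter layout (names, box constraints), an unpack(par) mapping to
# variance components + mean/threshold structure, and a moment-based start.

new_twin_model <- function(type, kind, traits, specs, covariates,
                           par_names, lower, upper, unpack, start,
                           pack = NULL, extra = list()) {
  structure(c(list(type = type, kind = kind, traits = traits, specs = specs,
                   covariates = covariates, par_names = par_names,
                   lower = lower, upper = upper, n_params = length(par_names),
                   unpack = unpack, start = start, pack = pack), extra),
            class = "twin_model")
}

#' @export
print.twin_model <- function(x, ...) {
  cat(sprintf("<twin_model> %s (%s), %d traits, %d free parameters%s\n",
              x$type, x$kind, length(x$traits), x$n_params,
              if (x$covariates) ", age/sex covariates" else ""))
  invisible(x)
}

vech_names <- function(prefix, traits) {
  pr <- vech_pairs(length(traits))
  vapply(seq_len(nrow(pr)), function(k)
    paste(prefix, traits[pr[k, 1L]], traits[pr[k, 2L]], sep = "."),
    character(1))
}

# shared mean/threshold parameter block ------------------------------------
mean_block <- function(specs, covariates) {
  cont <- specs$trait[specs$measure == "continuous"]
  ord <- specs$trait[specs$measure == "ordinal"]
  nms <- paste0("mu.", cont, recycle0 = TRUE)
  lo <- rep(-Inf, length(cont)); hi <- rep(Inf, length(cont))
  for (tr in ord) {
    k <- specs$n_cat[specs$trait == tr]
    nms <- c(nms, paste0("tau1.", tr),
             if (k > 2L) paste0("dtau", 2:(k - 1L), ".", tr))
    lo <- c(lo, -Inf, rep(1e-3, k - 2L))
    hi <- c(hi, rep(Inf, k - 1L))
  }
  if (covariates) {
    nms <- c(nms, paste0("bage.", specs$trait), paste0("bsex.", specs$trait))
    lo <- c(lo, rep(-Inf, 2L * nrow(specs)))
    hi <- c(hi, rep(Inf, 2L * nrow(specs)))
  }
  list(names = nms, lower = lo, upper = hi, cont = cont, ord = ord)
}

unpack_mean_block <- function(par, off, specs, covariates, age_transform) {
  cont <- specs$trait[specs$measure == "continuous"]
  ord <- specs$trait[specs$measure == "ordinal"]
  ic <- stats::setNames(rep(0, nrow(specs)), specs$trait)
  if (length(cont)) {
    ic[cont] <- par[off + seq_along(cont)]
    off <- off + length(cont)
  }
  thr <- list()
  for (tr in ord) {
    k <- specs$n_cat[specs$trait == tr]
    v <- par[off + seq_len(k - 1L)]
    off <- off + k - 1L
    thr[[tr]] <- cumsum(c(v[1L], if (k > 2L) v[-1L]))
  }
  ba <- bs <- NULL
  if (covariates) {
    p <- nrow(specs)
    ba <- stats::setNames(par[off + seq_len(p)], specs$trait); off <- off + p
    bs <- stats::setNames(par[off + seq_len(p)], specs$trait); off <- off + p
  }
  list(mt = mean_threshold_model(specs$trait, intercepts = ic[cont],
                                 beta_age = ba, beta_sex = bs,
                                 thresholds = thr,
                                 age_transform = age_transform),
       off = off)
}

# moment summaries used by the start functions ------------------------------
start_moments <- function(prep) {
  p <- prep$p
  Y <- prep$Y
  # standardize ordinal codes as rough liability proxies
  for (k in which(prep$specs$measure == "ordinal")) {
    for (col in c(k, p + k)) {
      v <- Y[, col]
      mu <- mean(v, na.rm = TRUE)
      s <- stats::sd(v, na.rm = TRUE)
      Y[, col] <- if (is.na(s) || s < 1e-8) v - mu else (v - mu) / s
    }
  }
  X1 <- Y[, seq_len(p), drop = FALSE]
  X2 <- Y[, p + seq_len(p), drop = FALSE]
  ind <- rbind(X1, X2)
  S_w <- stats::cov(ind, use = "pairwise.complete.obs")
  S_w[is.na(S_w)] <- 0
  cross <- function(cl) {
    i <- prep$cls == cl
    a <- rbind(X1[i, , drop = FALSE], X2[i, , drop = FALSE])
    b <- rbind(X2[i, , drop = FALSE], X1[i, , drop = FALSE])
    cc <- stats::cov(a, b, use = "pairwise.complete.obs")
    cc[is.na(cc)] <- 0
    (cc + t(cc)) / 2
  }
  list(S_w = S_w, C_mz = cross("MZ"), C_dz = cross("DZ"),
       means = colMeans(rbind(prep$Y[, seq_len(p), drop = FALSE],
                              prep$Y[, p + seq_len(p), drop = FALSE]),
                        na.rm = TRUE))
}

shrink_to_diag <- function(m, w) w * m + (1 - w) * diag(diag(m), nrow(m))

# thresholds start from observed category margins
threshold_start <- function(prep, tr) {
  k <- prep$specs$n_cat[prep$specs$trait == tr]
  i <- match(tr, prep$specs$trait)
  v <- c(prep$Y[, i], prep$Y[, prep$p + i])
  v <- v[!is.na(v)]
  cnt <- tabulate(v + 1L, nbins = k)
  cnt <- cnt + 0.5  # avoid empty extreme categories
  tau <- stats::qnorm(cumsum(cnt)[-k] / sum(cnt))
  c(tau[1L], if (k > 2L) pmax(diff(tau), 0.05))
}

#' Build a multivariate direct-symmetric twin model
#'
#' Free symmetric A / C-or-D / E covariance matrices over the p traits (the
#' saturated biometric covariance structure), with free intercepts for
#' continuous traits, free thresholds and unit total liability variance for
#' ordinal traits (the E diagonal is substituted as 1 minus the other
#' components), and optional linear age/sex mean covariates.
#'
#' @param kind `"ACE"`, `"ADE"`, `"AE"`, `"CE"` or `"E"`.
#' @param specs Measurement specification (default [psqi_specs()]); use a
#'   subset for fewer traits.
#' @param covariates Include age and sex mean effects (default `FALSE`).
#' @return A `twin_model`.
#' @export
build_multivariate <- function(kind = c("AE", "ACE", "ADE", "CE", "E"),
                               specs = psqi_specs(), covariates = FALSE) {
  kind <- match.arg(kind)
  traits <- specs$trait
  p <- length(traits)
  has_a <- kind %in% c("ACE", "ADE", "AE")
  has_cd <- kind %in% c("ACE", "ADE", "CE")
  cd_lab <- if (kind == "ADE") "D" else "C"
  ord <- which(specs$measure == "ordinal")
  pr <- vech_pairs(p)
  diag_idx <- which(pr[, 1L] == pr[, 2L])
  e_keep <- setdiff(seq_len(nrow(pr)), diag_idx[ord])  # E_ii substituted (ordinal)
  if (kind == "E") {
    # E-only with ordinal traits: E_ii fixed to 1 for identification
    e_keep <- setdiff(seq_len(nrow(pr)), diag_idx[ord])
  }
  nmA <- if (has_a) vech_names("A", traits) else character(0)
  nmC <- if (has_cd) vech_names(cd_lab, traits) else character(0)
  nmE <- vech_names("E", traits)[e_keep]
  mb <- mean_block(specs, covariates)
  par_names <- c(nmA, nmC, nmE, mb$names)
  lower <- c(rep(-Inf, length(nmA) + length(nmC)), rep(-Inf, length(nmE)),
             mb$lower)
  upper <- c(rep(Inf, length(nmA) + length(nmC) + length(nmE)), mb$upper)
  # E diagonal entries that remain free must stay positive
  e_free_diag <- match(vech_names("E", traits)[setdiff(diag_idx, diag_idx[ord])],
                       par_names)
  lower[e_free_diag] <- 1e-6

  nA <- length(nmA); nC <- length(nmC); nE <- length(nmE)
  unpack <- function(par, age_transform = c(0, 1)) {
    off <- 0L
    A <- CorD <- NULL
    if (has_a) { A <- unvech(par[off + seq_len(nA)], p); off <- off + nA }
    if (has_cd) { CorD <- unvech(par[off + seq_len(nC)], p); off <- off + nC }
    ev <- numeric(nrow(pr))
    ev[e_keep] <- par[off + seq_len(nE)]
    off <- off + nE
    E <- unvech(ev, p)
    pen <- 0
    for (i in ord) {
      sub <- 1 - (if (has_a) A[i, i] else 0) - (if (has_cd) CorD[i, i] else 0)
      if (sub < 1e-4) { pen <- pen + (1e-4 - sub); sub <- 1e-4 }
      E[i, i] <- sub
    }
    mbu <- unpack_mean_block(par, off, specs, covariates, age_transform)
    vc <- variance_components(kind = kind, A = A, CorD = CorD, E = E,
                              traits = traits)
    list(vc = vc, mt = mbu$mt, penalty = pen)
  }

  pack <- function(vc, mt = NULL) {
    stopifnot(vc$kind == kind)
    par <- c(if (has_a) vech(vc$A), if (has_cd) vech(vc$CorD),
             vech(vc$E)[e_keep])
    if (is.null(mt)) {
      par <- c(par, rep(0, length(mb$names)))
    } else {
      mu <- mt$intercepts[mb$cont]
      thr <- unlist(lapply(mb$ord, function(tr) {
        tau <- mt$thresholds[[tr]]
        c(tau[1L], if (length(tau) > 1L) diff(tau))
      }))
      par <- c(par, mu, thr,
               if (covariates) c(mt$beta_age, mt$beta_sex))
    }
    stats::setNames(par, par_names)
  }

  start <- function(prep) {
    sm <- start_moments(prep)
    A0 <- C0 <- matrix(0, p, p)
    if (kind == "AE") {
      A0 <- 2 * (sm$C_mz - sm$C_dz)
    } else if (kind == "ACE") {
      A0 <- 2 * (sm$C_mz - sm$C_dz)
      C0 <- 2 * sm$C_dz - sm$C_mz
    } else if (kind == "ADE") {
      A0 <- 4 * sm$C_dz - sm$C_mz
      C0 <- 2 * sm$C_mz - 4 * sm$C_dz
    } else if (kind == "CE") {
      C0 <- (sm$C_mz + sm$C_dz) / 2
    }
    E0 <- sm$S_w - A0 - C0
    # tame moment noise: shrink components, then force E and the total PD
    A0 <- shrink_to_diag(A0, 0.85); C0 <- shrink_to_diag(C0, 0.85)
    for (i in 1:6) {
      if (min_eigval(E0) > 0.02 * mean(diag(sm$S_w))) break
      A0 <- shrink_to_diag(0.9 * A0, 0.9)
      C0 <- shrink_to_diag(0.9 * C0, 0.9)
      E0 <- sm$S_w - A0 - C0
    }
    if (min_eigval(E0) < 1e-3)
      E0 <- E0 + (1e-3 - min_eigval(E0)) * diag(p)
    # ordinal traits: diagonal on the unit liability scale
    for (i in ord) {
      A0[i, i] <- min(max(A0[i, i], 0.05), 0.85)
      if (has_cd) C0[i, i] <- min(max(C0[i, i], 0), 0.4)
    }
    par <- c(if (has_a) vech(A0), if (has_cd) vech(C0), vech(E0)[e_keep])
    mu0 <- sm$means[specs$measure == "continuous"]
    thr0 <- unlist(lapply(mb$ord, function(tr) threshold_start(prep, tr)))
    par <- c(par, mu0, thr0, if (covariates) rep(0, 2L * p))
    pmin(pmax(stats::setNames(par, par_names), lower + 1e-6), upper - 1e-6)
  }

  new_twin_model("multivariate", kind, traits, specs, covariates,
                 par_names, lower, upper, unpack, start, pack)
}

#' Cole 3-factor assignment of the PSQI components
#'
#' The alternative 3-cluster structure: a sleep-efficiency factor (sleep
#' duration, habitual sleep efficiency), a perceived-sleep-quality factor
#' (subjective quality, latency, medication use) and a daily-disturbances
#' factor (disturbances, daytime dysfunction).
#'
#' @return Named list mapping factor name to trait names.
#' @export
cole_structure <- function() {
  list(sleep_efficiency = c("duration", "efficiency"),
       perceived_quality = c("quality", "latency", "medication"),
       daily_disturbances = c("disturbances", "daytime"))
}

# loading matrix pattern from a factor assignment
assignment_matrix <- function(structure, traits) {
  nf <- length(structure)
  L <- matrix(0L, length(traits), nf,
              dimnames = list(traits, names(structure)))
  for (f in seq_len(nf)) {
    miss <- setdiff(structure[[f]], traits)
    if (length(miss)) stop_input("unknown trait(s) in structure: %s",
                                 paste(miss, collapse = ", "))
    L[structure[[f]], f] <- 1L
  }
  un <- traits[rowSums(L) == 0L]
  if (length(un)) stop_input("trait(s) not assigned to any factor: %s",
                             paste(un, collapse = ", "))
  if (any(rowSums(L) > 1L)) stop_input("each trait must load on exactly one factor")
  L
}

#' Build a common-pathway model
#'
#' One (or three, under the Cole assignment) latent phenotype(s), each with
#' its own additive-genetic and non-shared-environment variance summing to
#' 1 (unit latent variance identifies the scale, so the latent h2 is
#' directly readable), transmitting to the traits through free loadings;
#' each trait keeps specific A and E residual variances. In the 3-factor
#' case the latent A parts and E parts are each allowed a free correlation
#' structure across factors (`correlated_factors = FALSE` forces
#' independence). Sign indeterminacy is resolved by constraining the first
#' loading of each factor to be nonnegative.
#'
#' @param structure Named list factor -> traits; default a single factor
#'   over all seven components.
#' @param specs Measurement specification.
#' @param covariates Include age/sex mean effects.
#' @param correlated_factors Allow latent factor correlations (3-factor
#'   case; default `TRUE`).
#' @return A `twin_model` of type `"common_pathway"`, kind AE.
#' @export
build_common_pathway <- function(structure = list(sleep_quality = psqi_specs()$trait),
                                 specs = psqi_specs(), covariates = FALSE,
                                 correlated_factors = TRUE) {
  traits <- specs$trait
  p <- length(traits)
  L <- assignment_matrix(structure, traits)
  nf <- ncol(L)
  first_of_factor <- vapply(seq_len(nf), function(f) which(L[, f] == 1L)[1L],
                            integer(1))
  ord <- which(specs$measure == "ordinal")
  nfc <- if (nf > 1L && correlated_factors) nf * (nf - 1L) / 2L else 0L
  nmL <- paste0("lambda.", traits)
  nmA <- paste0("aL2.", colnames(L))
  nmRA <- if (nfc) vech_names("rAf", colnames(L))[vech_pairs(nf)[, 1] !=
                                                    vech_pairs(nf)[, 2]] else character(0)
  nmRE <- if (nfc) sub("^rAf", "rEf", nmRA) else character(0)
  nmAS <- paste0("as.", traits)
  nmES <- paste0("es.", if (length(ord)) traits[-ord] else traits, recycle0 = TRUE)
  mb <- mean_block(specs, covariates)
  par_names <- c(nmL, nmA, nmRA, nmRE, nmAS, nmES, mb$names)
  lower <- c(rep(-Inf, p), rep(0, nf), rep(-0.99, 2L * nfc),
             rep(0, p), rep(1e-6, length(nmES)), mb$lower)
  upper <- c(rep(Inf, p), rep(1, nf), rep(0.99, 2L * nfc),
             rep(Inf, p), rep(Inf, length(nmES)), mb$upper)
  lower[first_of_factor] <- 0  # sign convention

  unpack <- function(par, age_transform = c(0, 1)) {
    off <- 0L
    lam <- par[off + seq_len(p)]; off <- off + p
    aL2 <- par[off + seq_len(nf)]; off <- off + nf
    RA <- RE <- diag(nf)
    pen <- 0
    if (nfc) {
      pairs_f <- vech_pairs(nf)
      offdiag <- which(pairs_f[, 1L] != pairs_f[, 2L])
      ra <- par[off + seq_len(nfc)]; off <- off + nfc
      re <- par[off + seq_len(nfc)]; off <- off + nfc
      for (k in seq_along(offdiag)) {
        i <- pairs_f[offdiag[k], 1L]; j <- pairs_f[offdiag[k], 2L]
        RA[i, j] <- RA[j, i] <- ra[k]
        RE[i, j] <- RE[j, i] <- re[k]
      }
      if (min_eigval(RA) < 1e-6) pen <- pen + (1e-6 - min_eigval(RA))
      if (min_eigval(RE) < 1e-6) pen <- pen + (1e-6 - min_eigval(RE))
    }
    a_s <- par[off + seq_len(p)]; off <- off + p
    e_s <- stats::setNames(rep(0, p), traits)
    n_es <- length(nmES)
    cont_or_all <- if (length(ord)) seq_len(p)[-ord] else seq_len(p)
    e_s[cont_or_all] <- par[off + seq_len(n_es)]; off <- off + n_es
    Lam <- L * lam
    sa <- sqrt(aL2); se <- sqrt(1 - aL2)
    SA <- (sa %o% sa) * RA
    SE <- (se %o% se) * RE
    A <- Lam %*% SA %*% t(Lam) + diag(a_s, p)
    E <- Lam %*% SE %*% t(Lam) + diag(e_s, p)
    for (i in ord) {
      common_i <- (Lam %*% (SA + SE) %*% t(Lam))[i, i]
      sub <- 1 - common_i - a_s[i]
      if (sub < 1e-4) { pen <- pen + (1e-4 - sub); sub <- 1e-4 }
      E[i, i] <- (Lam %*% SE %*% t(Lam))[i, i] + sub
    }
    mbu <- unpack_mean_block(par, off, specs, covariates, age_transform)
    vc <- variance_components("AE", A = (A + t(A)) / 2, E = (E + t(E)) / 2,
                              traits = traits)
    list(vc = vc, mt = mbu$mt, penalty = pen,
         pathway = list(loadings = Lam, latent_a2 = aL2, RA = RA, RE = RE,
                        specific_a = a_s, specific_e = e_s))
  }

  start <- function(prep) {
    sm <- start_moments(prep)
    sds <- sqrt(pmax(diag(sm$S_w), 1e-4))
    R <- stats::cov2cor(sm$S_w + diag(1e-6, p))
    lam0 <- numeric(p)
    for (f in seq_len(nf)) {
      tr_f <- which(L[, f] == 1L)
      Rf <- R[tr_f, tr_f, drop = FALSE]
      if (length(tr_f) == 1L) { lam0[tr_f] <- 0.6 * sds[tr_f]; next }
      ev <- eigen(Rf, symmetric = TRUE)
      v <- ev$vectors[, 1L]
      if (v[1L] < 0) v <- -v
      lam0[tr_f] <- pmax(pmin(v * sqrt(ev$values[1L]), 0.95), -0.95) * sds[tr_f]
    }
    as0 <- 0.12 * diag(sm$S_w)
    es0 <- pmax(diag(sm$S_w) - lam0^2 - as0, 0.15 * diag(sm$S_w))
    cont_or_all <- if (length(ord)) seq_len(p)[-ord] else seq_len(p)
    par <- c(lam0, rep(0.35, nf), rep(0.25, 2L * nfc), as0, es0[cont_or_all])
    mu0 <- sm$means[specs$measure == "continuous"]
    thr0 <- unlist(lapply(mb$ord, function(tr) threshold_start(prep, tr)))
    par <- c(par, mu0, thr0, if (covariates) rep(0, 2L * p))
    pmin(pmax(stats::setNames(par, par_names), lower + 1e-6), upper - 1e-6)
  }

  new_twin_model("common_pathway", "AE", traits, specs, covariates,
                 par_names, lower, upper, unpack, start,
                 extra = list(structure = structure, n_factors = nf,
                              assignment = L))
}

#' Build an independent-pathway model
#'
#' One common additive-genetic factor and one common non-shared-environment
#' factor load directly on every trait (no intervening latent phenotype);
#' each trait keeps specific A and E variances. The first loading of each
#' common factor is constrained nonnegative to fix the sign.
#'
#' @param specs Measurement specification.
#' @param covariates Include age/sex mean effects.
#' @return A `twin_model` of type `"independent_pathway"`, kind AE.
#' @export
build_independent_pathway <- function(specs = psqi_specs(), covariates = FALSE) {
  traits <- specs$trait
  p <- length(traits)
  if (p < 2L) stop_input("independent-pathway model needs at least 2 traits")
  ord <- which(specs$measure == "ordinal")
  nmFA <- paste0("fa.", traits)
  nmFE <- paste0("fe.", traits)
  nmAS <- paste0("as.", traits)
  nmES <- paste0("es.", if (length(ord)) traits[-ord] else traits, recycle0 = TRUE)
  mb <- mean_block(specs, covariates)
  par_names <- c(nmFA, nmFE, nmAS, nmES, mb$names)
  lower <- c(rep(-Inf, 2L * p), rep(0, p), rep(1e-6, length(nmES)), mb$lower)
  upper <- c(rep(Inf, 2L * p + p + length(nmES)), mb$upper)
  lower[c(1L, p + 1L)] <- 0  # sign convention on the first loadings

  unpack <- function(par, age_transform = c(0, 1)) {
    off <- 0L
    fa <- par[off + seq_len(p)]; off <- off + p
    fe <- par[off + seq_len(p)]; off <- off + p
    a_s <- par[off + seq_len(p)]; off <- off + p
    e_s <- stats::setNames(rep(0, p), traits)
    cont_or_all <- if (length(ord)) seq_len(p)[-ord] else seq_len(p)
    n_es <- length(cont_or_all)
    e_s[cont_or_all] <- par[off + seq_len(n_es)]; off <- off + n_es
    pen <- 0
    A <- fa %o% fa + diag(a_s, p)
    E <- fe %o% fe + diag(e_s, p)
    for (i in ord) {
      sub <- 1 - fa[i]^2 - fe[i]^2 - a_s[i]
      if (sub < 1e-4) { pen <- pen + (1e-4 - sub); sub <- 1e-4 }
      E[i, i] <- fe[i]^2 + sub
    }
    mbu <- unpack_mean_block(par, off, specs, covariates, age_transform)
    vc <- variance_components("AE", A = A, E = E, traits = traits)
    list(vc = vc, mt = mbu$mt, penalty = pen,
         pathway = list(common_a = fa, common_e = fe,
                        specific_a = a_s, specific_e = e_s))
  }

  start <- function(prep) {
    sm <- start_moments(prep)
    sds <- sqrt(pmax(diag(sm$S_w), 1e-4))
    R <- stats::cov2cor(sm$S_w + diag(1e-6, p))
    ev <- eigen(R, symmetric = TRUE)
    v <- ev$vectors[, 1L]
    if (v[1L] < 0) v <- -v
    base <- pmax(pmin(v * sqrt(ev$values[1L]), 0.95), -0.95) * sds
    fa0 <- sqrt(0.35) * base
    fe0 <- sqrt(0.65) * base
    as0 <- 0.12 * diag(sm$S_w)
    cont_or_all <- if (length(ord)) seq_len(p)[-ord] else seq_len(p)
    es0 <- pmax(diag(sm$S_w) - fa0^2 - fe0^2 - as0, 0.15 * diag(sm$S_w))
    par <- c(fa0, fe0, as0, es0[cont_or_all])
    mu0 <- sm$means[specs$measure == "continuous"]
    thr0 <- unlist(lapply(mb$ord, function(tr) threshold_start(prep, tr)))
    par <- c(par, mu0, thr0, if (covariates) rep(0, 2L * p))
    pmin(pmax(stats::setNames(par, par_names), lower + 1e-6), upper - 1e-6)
  }

  new_twin_model("independent_pathway", "AE", traits, specs, covariates,
                 par_names, lower, upper, unpack, start)
}

#' Standardized common/specific variance shares of a pathway fit
#'
#' Decomposes each trait's variance into common-A, common-E, specific-A
#' and specific-E shares (summing to 1).
#'
#' @param fit A `twin_fit` of a pathway model.
#' @return Matrix with one row per trait.
#' @export
pathway_shares <- function(fit) {
  stopifnot(inherits(fit, "twin_fit"),
            fit$model$type %in% c("common_pathway", "independent_pathway"))
  um <- fit$model$unpack(fit$estimates, fit$age_transform)
  pw <- um$pathway
  p <- length(fit$model$traits)
  if (fit$model$type == "common_pathway") {
    Lam <- pw$loadings
    sa <- sqrt(pw$latent_a2); se <- sqrt(1 - pw$latent_a2)
    commonA <- diag(Lam %*% ((sa %o% sa) * pw$RA) %*% t(Lam))
    commonE <- diag(Lam %*% ((se %o% se) * pw$RE) %*% t(Lam))
  } else {
    commonA <- pw$common_a^2
    commonE <- pw$common_e^2
  }
  specA <- pw$specific_a
  specE <- diag(um$vc$E) - commonE
  tot <- commonA + commonE + specA + specE
  out <- cbind(common_a = commonA, common_e = commonE,
               specific_a = specA, specific_e = specE) / tot
  rownames(out) <- fit$model$traits
  out
}

# start vectors carried across the nested family ---------------------------
ip_start_from_cp <- function(cp_fit, ip_model, prep) {
  um <- cp_fit$model$unpack(cp_fit$estimates, cp_fit$age_transform)
  pw <- um$pathway
  if (cp_fit$model$n_factors != 1L) return(NULL)
  lam <- pw$loadings[, 1L]
  fa <- lam * sqrt(pw$latent_a2)
  fe <- lam * sqrt(1 - pw$latent_a2)
  if (fa[1L] < 0) fa <- -fa
  if (fe[1L] < 0) fe <- -fe
  p <- length(lam)
  ord <- which(ip_model$specs$measure == "ordinal")
  cont_or_all <- if (length(ord)) seq_len(p)[-ord] else seq_len(p)
  e_s <- diag(um$vc$E) - fe^2
  par <- c(fa, fe, pmax(pw$specific_a, 0),
           pmax(e_s[cont_or_all], 1e-4))
  par <- c(par, mean_tail(cp_fit, ip_model))
  pmin(pmax(par, ip_model$lower + 1e-6), ip_model$upper - 1e-6)
}

mv_start_from_ip <- function(ip_fit, mv_model, prep) {
  um <- ip_fit$model$unpack(ip_fit$estimates, ip_fit$age_transform)
  par <- c(vech(um$vc$A), vech_keepE(mv_model, um$vc$E), mean_tail(ip_fit, mv_model))
  pmin(pmax(par, mv_model$lower + 1e-6), mv_model$upper - 1e-6)
}

vech_keepE <- function(mv_model, E) {
  keep <- grep("^E\\.", mv_model$par_names)
  full <- vech_names("E", mv_model$traits)
  vech(E)[match(mv_model$par_names[keep], full)]
}

# mean/threshold parameter tail copied between models of the same specs
mean_tail <- function(fit, model) {
  mb_names <- model$par_names[!grepl("^(A|C|D|E|lambda|aL2|rAf|rEf|as|es|fa|fe)\\.",
                                     model$par_names)]
  src <- fit$estimates[mb_names]
  src[is.na(src)] <- 0
  unname(src)
}

#' Fit and compare the model family on one dataset
#'
#' Fits the requested models and returns a comparison table ranked by AIC,
#' with likelihood-ratio tests where models are nested (common pathway is
#' nested in independent pathway, which is nested in the free multivariate
#' structure; each richer model is additionally started from the best
#' nested solution, which also enforces the -2LL ordering multivariate <=
#' independent <= common up to optimizer tolerance).
#'
#' @param data A [twin_dataset()].
#' @param models Character subset of `c("multivariate_AE", "independent_pathway",
#'   "common_pathway_1", "common_pathway_3")`.
#' @param specs Measurement specification.
#' @param covariates Include age/sex covariates in all models.
#' @param restarts,seed Passed to [fit_twin_model()].
#' @return List with `table` (data frame: model, minus2LL, n_params, AIC,
#'   deltaAIC, LRT columns vs the multivariate model, failure flags) and
#'   `fits` (named list of `twin_fit` objects).
#' @export
selection_driver <- function(data,
                             models = c("multivariate_AE", "independent_pathway",
                                        "common_pathway_1"),
                             specs = psqi_specs(), covariates = FALSE,
                             restarts = 1L, seed = 1L) {
  fits <- list()
  safe_fit <- function(model, start = NULL) {
    tryCatch(fit_twin_model(model, data, restarts = restarts, seed = seed,
                            start = start),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "twin_fit_failure"))
  }
  better <- function(a, b) {
    ok_a <- inherits(a, "twin_fit"); ok_b <- inherits(b, "twin_fit")
    if (!ok_a) return(b)
    if (!ok_b) return(a)
    if (a$minus2LL <= b$minus2LL) a else b
  }
  prep <- NULL
  if ("common_pathway_1" %in% models)
    fits$common_pathway_1 <- safe_fit(build_common_pathway(
      structure = list(sleep_quality = specs$trait), specs = specs,
      covariates = covariates))
  if ("common_pathway_3" %in% models)
    fits$common_pathway_3 <- safe_fit(build_common_pathway(
      structure = cole_structure(), specs = specs, covariates = covariates))
  if ("independent_pathway" %in% models) {
    ip_model <- build_independent_pathway(specs = specs, covariates = covariates)
    f_own <- safe_fit(ip_model)
    f_seed <- NULL
    if (inherits(fits$common_pathway_1, "twin_fit")) {
      prep <- prep %||% prep_likelihood(ip_model, data)
      s <- ip_start_from_cp(fits$common_pathway_1, ip_model, prep)
      if (!is.null(s)) f_seed <- safe_fit(ip_model, start = s)
    }
    fits$independent_pathway <- better(f_own, f_seed %||% f_own)
  }
  if ("multivariate_AE" %in% models) {
    mv_model <- build_multivariate("AE", specs = specs, covariates = covariates)
    f_own <- safe_fit(mv_model)
    f_seed <- NULL
    if (inherits(fits$independent_pathway, "twin_fit")) {
      s <- mv_start_from_ip(fits$independent_pathway, mv_model, prep)
      f_seed <- safe_fit(mv_model, start = s)
    }
    fits$multivariate_AE <- better(f_own, f_seed %||% f_own)
  }
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (!inherits(f, "twin_fit"))
      return(data.frame(model = nm, minus2LL = NA, n_params = NA, AIC = NA,
                        failed = TRUE, stringsAsFactors = FALSE))
    data.frame(model = nm, minus2LL = f$minus2LL, n_params = f$n_params,
               AIC = f$AIC, failed = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$deltaAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  ref <- fits$multivariate_AE
  tab$lrt_chi2 <- tab$lrt_df <- tab$lrt_p <- NA_real_
  if (inherits(ref, "twin_fit")) {
    for (i in seq_len(nrow(tab))) {
      nm <- tab$model[i]
      if (nm == "multivariate_AE" || tab$failed[i]) next
      cmp <- tryCatch(compare_fits(ref, fits[[nm]]), error = function(e) NULL)
      if (!is.null(cmp)) {
        tab$lrt_chi2[i] <- cmp$chi2; tab$lrt_df[i] <- cmp$df
        tab$lrt_p[i] <- cmp$p
      }
    }
  }
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
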