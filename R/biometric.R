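#' Variance components of a multivariate twin model
#'
#' Container for the additive-genetic (A), shared-environment (C) or
#' dominance (D), and non-shared-environment (E) covariance matrices over p
#' traits under the direct symmetric parameterization: each component is a
#' free symmetric matrix, and only the total phenotypic covariance
#' `A + C/D + E` is required to be positive semidefinite. Individual
#' components may be indefinite during estimation; this avoids the type-I
#' error and bias problems of boundary-constrained (Cholesky)
#' parameterizations.
#'
#' @param kind One of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`.
#' @param A p x p symmetric additive-genetic covariance (omit for CE/E).
#' @param CorD p x p symmetric shared-environment (ACE/CE) or dominance
#'   (ADE) covariance; `NULL` for AE/E.
#' @param E p x p symmetric non-shared-environment covariance; diagonal must
#'   be strictly positive.
#' @param traits Length-p character vector of trait names.
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(kind = c("ACE", "ADE", "AE", "CE", "E"),
                                A = NULL, CorD = NULL, E, traits = NULL) {
  kind <- match.arg(kind)
  E <- as.matrix(E)
  p <- nrow(E)
  if (!is_symmetric_num(E)) stop_input("E must be symmetric")
  if (any(diag(E) <= 0)) stop_input("diagonal of E must be strictly positive")
  has_a <- kind %in% c("ACE", "ADE", "AE")
  has_cd <- kind %in% c("ACE", "ADE", "CE")
  if (has_a) {
    if (is.null(A)) stop_input("kind %s requires A", kind)
    A <- as.matrix(A)
    if (!is_symmetric_num(A) || nrow(A) != p) stop_input("A must be symmetric p x p")
  } else {
    if (!is.null(A)) stop_input("kind %s takes no A component", kind)
    A <- matrix(0, p, p)
  }
  if (has_cd) {
    if (is.null(CorD)) stop_input("kind %s requires a C or D component", kind)
    CorD <- as.matrix(CorD)
    if (!is_symmetric_num(CorD) || nrow(CorD) != p)
      stop_input("C/D must be symmetric p x p")
  } else {
    if (!is.null(CorD)) stop_input("kind %s takes no C/D component", kind)
    CorD <- matrix(0, p, p)
  }
  traits <- traits %||% rownames(E) %||% paste0("t", seq_len(p))
  if (length(traits) != p) stop_input("traits must have length %d", p)
  dimnames(A) <- dimnames(CorD) <- dimnames(E) <- list(traits, traits)
  structure(list(kind = kind, A = A, CorD = CorD, E = E, traits = traits, p = p),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> kind=%s, p=%d traits\n", x$kind, x$p))
  cat("standardized diagonal:\n")
  print(round(standardize_components(x), 3))
  invisible(x)
}

#' Total phenotypic covariance implied by a set of variance components
#'
#' @param vc A [variance_components()] object.
#' @return The p x p matrix `A + C/D + E`.
#' @export
total_covariance <- function(vc) vc$A + vc$CorD + vc$E

# cross-twin coefficients on (A, C-or-D) for a zygosity group label
zygosity_coefs <- function(kind, zygosity) {
  groups <- c("MZm", "MZf", "DZm", "DZf", "DOS", "MZ", "DZ")
  if (!zygosity %in% groups)
    stop_input("unknown zygosity label '%s' (expected one of %s)",
               zygosity, paste(groups, collapse = ", "))
  mz <- zygosity %in% c("MZm", "MZf", "MZ")
  a <- if (mz) 1 else 0.5
  cd <- if (kind == "ADE") (if (mz) 1 else 0.25) else 1
  c(a = a, cd = cd)
}

#' Expected twin-pair covariance matrix for a zygosity group
#'
#' Builds the 2p x 2p covariance of the stacked phenotype vector (twin 1's
#' p traits, then twin 2's). Within-twin blocks are `A + C/D + E`.
#' Cross-twin blocks reflect genetic sharing: MZ pairs share all additive
#' and dominance variance (coefficients 1, 1), DZ pairs share half the
#' additive and a quarter of the dominance variance (0.5, 0.25); shared
#' environment C contributes fully to both.
#'
#' @param vc A [variance_components()] object.
#' @param zygosity `"MZ"`, `"DZ"`, or one of the five cohort group labels
#'   `"MZm"`, `"MZf"`, `"DZm"`, `"DZf"`, `"DOS"`.
#' @return Symmetric 2p x 2p matrix.
#' @export
expected_twin_covariance <- function(vc, zygosity) {
  stopifnot(inherits(vc, "variance_components"))
  cf <- zygosity_coefs(vc$kind, zygosity)
  within <- total_covariance(vc)
  cross <- cf["a"] * vc$A +
    (if (vc$kind %in% c("ACE", "CE")) vc$CorD
     else if (vc$kind == "ADE") cf["cd"] * vc$CorD
     else matrix(0, vc$p, vc$p))
  out <- rbind(cbind(within, cross), cbind(t(cross), within))
  nm <- c(paste0(vc$traits, "_1"), paste0(vc$traits, "_2"))
  dimnames(out) <- list(nm, nm)
  out
}

#' Standardized variance components per trait
#'
#' @param vc A [variance_components()] object.
#' @return Matrix with one row per trait and columns `h2`, `c2`/`d2`
#'   (when present) and `e2`, each the component's share of the total
#'   phenotypic variance; rows sum to 1.
#' @export
standardize_components <- function(vc) {
  tot <- diag(total_covariance(vc))
  if (any(tot <= 0)) stop_input("degenerate trait: zero total variance")
  cols <- list(h2 = diag(vc$A) / tot)
  if (vc$kind %in% c("ACE", "CE")) cols$c2 <- diag(vc$CorD) / tot
  if (vc$kind == "ADE") cols$d2 <- diag(vc$CorD) / tot
  cols$e2 <- diag(vc$E) / tot
  out <- do.call(cbind, cols)
  rownames(out) <- vc$traits
  if (vc$kind %in% c("AE", "E")) out <- out[, c("h2", "e2"), drop = FALSE]
  out
}

#' Etiological (genetic and environmental) correlation matrices
#'
#' The correlation between the latent influences of one kind on two traits:
#' `rA_ij = A_ij / sqrt(A_ii * A_jj)` and analogously for C/D and E. Values
#' range from -1 to 1; 0 means no overlap of the influences, 1 or -1
#' complete overlap.
#'
#' @param vc A [variance_components()] object.
#' @return List of matrices `rA`, `rCorD` (if present) and `rE`. Entries
#'   whose defining variances are zero or negative are `NA` and flagged in
#'   the `undefined` attribute.
#' @export
etiological_correlations <- function(vc) {
  comp_cor <- function(m) {
    d <- diag(m)
    bad <- d <= 0
    s <- sqrt(ifelse(bad, NA_real_, d))
    r <- m / (s %o% s)
    diag(r) <- ifelse(bad, NA_real_, 1)
    attr(r, "undefined") <- vc$traits[bad]
    r
  }
  out <- list(rA = comp_cor(vc$A))
  if (vc$kind %in% c("ACE", "ADE", "CE")) out$rCorD <- comp_cor(vc$CorD)
  out$rE <- comp_cor(vc$E)
  if (vc$kind %in% c("CE", "E")) out$rA <- NULL
  out
}

#' Bivariate decomposition of a phenotypic correlation
#'
#' Splits the model-implied phenotypic correlation between two traits into
#' its additive-genetic and non-shared-environmental parts:
#' `contribA = rA * sqrt(h2_i * h2_j)` and `contribE = rE * sqrt(e2_i *
#' e2_j)`, with `rPH = contribA + contribE` (plus a C/D term when present).
#' `propA = contribA / rPH` is the bivariate heritability: the share of the
#' phenotypic correlation explained by genes. When the two contributions
#' have opposite signs a proportion is not meaningful; the signed
#' contributions are then the reported quantities and `propA`/`propE` are
#' `NA` with `mixed_sign = TRUE`.
#'
#' @param h2_i,h2_j Standardized genetic variances of the two traits.
#' @param e2_i,e2_j Standardized non-shared-environment variances.
#' @param rA_ij,rE_ij Genetic and environmental correlations.
#' @param c2_i,c2_j,rC_ij Optional shared-environment (or dominance) parts.
#' @return List with `contribA`, `contribC` (if supplied), `contribE`,
#'   `rPH`, `propA`, `propE`, and flags `mixed_sign`, `zero_rph`.
#' @export
decompose_phenotypic_correlation <- function(h2_i, h2_j, e2_i, e2_j,
                                             rA_ij, rE_ij,
                                             c2_i = 0, c2_j = 0, rC_ij = 0) {
  chk01 <- function(x, nm) if (any(x < 0 | x > 1)) stop_input("%s must lie in [0, 1]", nm)
  chk01(c(h2_i, h2_j), "h2"); chk01(c(e2_i, e2_j), "e2"); chk01(c(c2_i, c2_j), "c2")
  if (any(abs(c(rA_ij, rE_ij, rC_ij)) > 1)) stop_input("correlations must lie in [-1, 1]")
  contribA <- rA_ij * sqrt(h2_i * h2_j)
  contribC <- rC_ij * sqrt(c2_i * c2_j)
  contribE <- rE_ij * sqrt(e2_i * e2_j)
  rPH <- contribA + contribC + contribE
  parts <- c(contribA, contribE, if (c2_i > 0 || c2_j > 0) contribC)
  nz <- parts[abs(parts) > 1e-12]
  mixed <- length(nz) > 1 && length(unique(sign(nz))) > 1
  zero_rph <- abs(rPH) < 1e-12
  if (mixed || zero_rph) {
    propA <- propE <- NA_real_
  } else {
    propA <- contribA / rPH
    propE <- contribE / rPH
  }
  list(contribA = contribA, contribC = contribC, contribE = contribE,
       rPH = rPH, propA = propA, propE = propE,
       mixed_sign = mixed, zero_rph = zero_rph)
}

#' Full decomposition table for a set of variance components
#'
#' The per-trait standardized variance components together with, for every
#' trait pair, the etiological correlations, the model-implied phenotypic
#' correlation, and the standardized covariance contributions and shares.
#'
#' @param vc A [variance_components()] object.
#' @return An object of class `decomposition_table`: list with `traits`
#'   (per-trait standardized components) and `pairs` (one row per unordered
#'   trait pair).
#' @export
decomposition_table <- function(vc) {
  std <- standardize_components(vc)
  ec <- etiological_correlations(vc)
  p <- vc$p
  has_c <- vc$kind %in% c("ACE", "ADE", "CE")
  rows <- list()
  for (j in seq_len(p - 1)) for (i in seq((j + 1), p)) {
    d <- decompose_phenotypic_correlation(
      h2_i = std[i, "h2"], h2_j = std[j, "h2"],
      e2_i = std[i, "e2"], e2_j = std[j, "e2"],
      rA_ij = if (is.null(ec$rA)) 0 else ec$rA[i, j],
      rE_ij = ec$rE[i, j],
      c2_i = if (has_c) std[i, 2] else 0,
      c2_j = if (has_c) std[j, 2] else 0,
      rC_ij = if (has_c) ec$rCorD[i, j] else 0)
    rows[[length(rows) + 1L]] <- data.frame(
      trait_i = vc$traits[i], trait_j = vc$traits[j],
      rA = if (is.null(ec$rA)) NA_real_ else ec$rA[i, j],
      rC = if (has_c) ec$rCorD[i, j] else NA_real_,
      rE = ec$rE[i, j], rPH = d$rPH,
      contribA = d$contribA, contribC = d$contribC, contribE = d$contribE,
      propA = d$propA, propE = d$propE, mixed_sign = d$mixed_sign,
      stringsAsFactors = FALSE)
  }
  structure(list(traits = std, pairs = do.call(rbind, rows), kind = vc$kind),
            class = "decomposition_table")
}

#' @export
print.decomposition_table <- function(x, digits = 2, ...) {
  cat(sprintf("<decomposition_table> kind=%s\n", x$kind))
  cat("standardized variance components:\n")
  print(round(x$traits, digits))
  cat("pairwise decomposition:\n")
  df <- x$pairs
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a decomposition table to CSV files
#'
#' Serializes the per-trait standardized components and the pairwise
#' decomposition (correlations, contributions, shares) to two CSV files.
#'
#' @param x A [decomposition_table()] object.
#' @param path_traits,path_pairs Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_decomposition_csv <- function(x, path_traits, path_pairs) {
  stopifnot(inherits(x, "decomposition_table"))
  utils::write.csv(data.frame(trait = rownames(x$traits), x$traits,
                              row.names = NULL),
                   path_traits, row.names = FALSE)
  utils::write.csv(x$pairs, path_pairs, row.names = FALSE)
  invisible(c(path_traits, path_pairs))
}

#' Published multivariate AE estimates for the seven PSQI components
#'
#' Reference point estimates from a population-based middle-aged adult twin
#' cohort analyzed with the multivariate direct-symmetric AE model:
#' per-component heritabilities and the full matrices of genetic (rA),
#' non-shared environmental (rE) and phenotypic (rPH) correlations,
#' together with the printed 95% CIs of the genetic correlations. Used as
#' the default ground truth of the synthetic-cohort generator and as the
#' worked-example input for the bivariate decompositions.
#'
#' @return List with `h2` (named vector), `rA`, `rE`, `rPH` (7 x 7
#'   matrices) and `rA_ci` (list of `lo`/`hi` matrices).
#' @export
psqi_reference_estimates <- function() {
  traits <- psqi_components()
  h2 <- c(latency = 0.23, duration = 0.25, efficiency = 0.21,
          disturbances = 0.32, quality = 0.30, medication = 0.40,
          daytime = 0.36)
  mk <- function() {
    m <- diag(7)
    dimnames(m) <- list(traits, traits)
    m
  }
  rA <- mk(); rE <- mk(); rPH <- mk()
  rA_lo <- mk(); rA_hi <- mk(); diag(rA_lo) <- diag(rA_hi) <- NA
  set3 <- function(i, j, a, e, ph, alo, ahi) {
    rA[i, j] <<- rA[j, i] <<- a
    rE[i, j] <<- rE[j, i] <<- e
    rPH[i, j] <<- rPH[j, i] <<- ph
    rA_lo[i, j] <<- rA_lo[j, i] <<- alo
    rA_hi[i, j] <<- rA_hi[j, i] <<- ahi
  }
  set3("duration", "latency", -0.45, -0.27, -0.31, -0.69, -0.04)
  set3("efficiency", "latency", -0.42, -0.36, -0.38, -0.65, -0.09)
  set3("efficiency", "duration", 0.69, 0.63, 0.64, 0.45, 0.84)
  set3("disturbances", "latency", 0.36, 0.32, 0.33, 0.10, 0.55)
  set3("disturbances", "duration", -0.35, -0.30, -0.31, -0.60, -0.13)
  set3("disturbances", "efficiency", -0.39, -0.36, -0.36, -0.59, -0.16)
  set3("quality", "latency", 0.74, 0.36, 0.46, 0.49, 0.97)
  set3("quality", "duration", -0.66, -0.41, -0.48, -0.87, -0.46)
  set3("quality", "efficiency", -0.65, -0.41, -0.47, -0.81, -0.43)
  set3("quality", "disturbances", 0.69, 0.43, 0.51, 0.52, 0.84)
  set3("medication", "latency", 0.48, 0.18, 0.27, 0.19, 0.79)
  set3("medication", "duration", -0.26, 0.03, -0.06, -0.58, 0.10)
  set3("medication", "efficiency", -0.30, -0.17, -0.21, -0.63, 0.21)
  set3("medication", "disturbances", 0.50, 0.10, 0.24, 0.24, 0.89)
  set3("medication", "quality", 0.55, 0.31, 0.39, 0.20, 0.79)
  set3("daytime", "latency", 0.44, 0.03, 0.15, 0.06, 0.73)
  set3("daytime", "duration", -0.17, -0.22, -0.21, -0.47, 0.29)
  set3("daytime", "efficiency", -0.25, -0.16, -0.18, -0.67, 0.20)
  set3("daytime", "disturbances", 0.49, 0.23, 0.32, 0.14, 0.73)
  set3("daytime", "quality", 0.44, 0.34, 0.37, 0.08, 0.70)
  set3("daytime", "medication", 0.33, 0.19, 0.25, 0.02, 0.92)
  list(h2 = h2, rA = rA, rE = rE, rPH = rPH,
       rA_ci = list(lo = rA_lo, hi = rA_hi))
}

#' Reference variance components implied by the published estimates
#'
#' Converts the published heritabilities and etiological correlations into
#' AE covariance matrices on the unit-variance (liability) scale:
#' `A_ij = rA_ij * sqrt(h2_i * h2_j)`, `E_ij = rE_ij * sqrt(e2_i * e2_j)`.
#' Both matrices are positive definite as printed.
#'
#' @return A [variance_components()] object of kind `"AE"` with unit total
#'   variances.
#' @export
psqi_reference_components <- function() {
  ref <- psqi_reference_estimates()
  sa <- sqrt(ref$h2)
  se <- sqrt(1 - ref$h2)
  variance_components(kind = "AE",
                      A = ref$rA * (sa %o% sa),
                      E = ref$rE * (se %o% se),
                      traits = names(ref$h2))
}
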