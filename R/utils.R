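# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# half-vectorization index pairs (i <= j, column-major over the lower triangle)
vech_pairs <- function(p) {
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
}

# build a symmetric p x p matrix from its vech
unvech <- function(v, p) {
  m <- matrix(0, p, p)
  m[lower.tri(m, diag = TRUE)] <- NA  # placeholder to keep ordering explicit
  pr <- vech_pairs(p)
  for (k in seq_len(nrow(pr))) {
    m[pr[k, 1L], pr[k, 2L]] <- v[k]
    m[pr[k, 2L], pr[k, 1L]] <- v[k]
  }
  m
}

vech <- function(m) {
  pr <- vech_pairs(nrow(m))
  m[pr]
}

is_symmetric_num <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# smallest eigenvalue (symmetric part); used for PSD checks and penalties
min_eigval <- function(m) {
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# log-determinant and inverse via Cholesky; returns NULL if not PD
chol_safe <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  list(chol = ch, logdet = 2 * sum(log(diag(ch))), inv = chol2inv(ch))
}

stop_input <- function(...) stop(sprintf(...), call. = FALSE)
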