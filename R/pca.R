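#' Leading principal components of a relatedness matrix
#'
#' Eigenvectors of the GRM for the `k` largest eigenvalues, used as fixed
#' covariates against population stratification. Each column is unit-norm
#' with a deterministic sign convention: the entry of largest magnitude is
#' positive. If the spectrum is (near-)degenerate across the retained
#' components the basis of the tied subspace is arbitrary; a warning is
#' emitted.
#'
#' @param grm A `grm` object.
#' @param k Number of components, `k < n`.
#' @return An `n x k` matrix of eigenvector covariates.
#' @export
top_pcs <- function(grm, k) {
  A <- grm$A
  if (max(abs(A - t(A))) > 1e-8) stop("GRM is not symmetric")
  n <- nrow(A)
  stopifnot(k >= 1, k < n)
  e <- eigen(A, symmetric = TRUE)
  vals <- e$values[seq_len(min(k + 1, n))]
  if (k < n && abs(vals[k + 1] - vals[k]) < 1e-10 * max(abs(vals), 1)) {
    warning("degenerate eigenvalues at the component cutoff; ",
            "returned basis is arbitrary within the tied subspace")
  }
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("PC", seq_len(k))
  V
}
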