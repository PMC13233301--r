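# row-standardise a probes x samples matrix; constant rows are the caller's
# problem (they carry no component information)
standardise_rows <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  keep <- s > 0
  list(z = (x[keep, , drop = FALSE] - mu[keep]) / s[keep], kept = keep)
}

#' Reference-free cell-composition components (ReFACTor procedure)
#'
#' Estimates per-sample scores capturing nucleated cell-type composition
#' without a reference panel. Probes are standardised; a rank-`k` principal
#' approximation of the matrix is formed; probes are ranked by how well that
#' low-rank approximation reconstructs them (cell-composition-driven probes
#' reconstruct best because composition is the dominant low-rank structure);
#' a final PCA of the `t` best-reconstructed probes yields the sample
#' scores.
#'
#' @param beta Beta matrix (probes x samples), complete.
#' @param k Assumed number of cell types for the low-rank step (default 5).
#' @param t Number of best-reconstructed probes kept (default 500).
#' @param n_components Number of component score vectors returned (default
#'   10, the usual adjustment set).
#' @return Numeric matrix (samples x `n_components`), columns `cellPC1` ...;
#'   mutually orthogonal.
#' @export
refactor_components <- function(beta, k = 5, t = 500, n_components = 10) {
  if (k >= min(dim(beta))) abort("`k` must be smaller than both matrix dimensions")
  std <- standardise_rows(beta)
  if (nrow(std$z) == 0) abort("degenerate matrix: all probes are constant")
  z <- std$z
  t <- min(t, nrow(z))
  n_components <- min(n_components, ncol(z) - 1, t)

  sv <- svd(z, nu = k, nv = k)
  low_rank <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  dist <- sqrt(rowSums((z - low_rank)^2))
  keep <- order(dist)[seq_len(t)]

  sv2 <- svd(z[keep, , drop = FALSE], nu = 0, nv = n_components)
  scores <- sv2$v %*% diag(sv2$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(colnames(beta), paste0("cellPC", seq_len(n_components)))
  scores
}

#' Ancestry components from informative probes
#'
#' Principal-component scores computed on the submatrix of
#' ancestry-informative probes only, in the spirit of inferring genetic
#' ancestry structure from methylation at cis-genotype-driven CpGs.
#'
#' @param beta Beta matrix (probes x samples).
#' @param informative_probes Character vector of probe ids; ids absent from
#'   the matrix are skipped with a warning.
#' @param n_components Number of score vectors returned (default 10).
#' @return Numeric matrix (samples x components), columns `ancPC1` ...
#' @export
ancestry_components <- function(beta, informative_probes, n_components = 10) {
  present <- intersect(informative_probes, rownames(beta))
  if (length(present) == 0) abort("no informative probes present in the matrix")
  if (length(present) < length(informative_probes)) {
    warn(sprintf("%d informative probes absent from the matrix were skipped",
                 length(informative_probes) - length(present)))
  }
  std <- standardise_rows(beta[present, , drop = FALSE])
  if (nrow(std$z) == 0) abort("all informative probes are constant")
  z <- std$z
  n_components <- min(n_components, nrow(z), ncol(z) - 1)
  sv <- svd(z, nu = 0, nv = n_components)
  scores <- sv$v %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(colnames(beta), paste0("ancPC", seq_len(n_components)))
  scores
}
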