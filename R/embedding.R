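#' Embed genes into principal-component space
#'
#' Runs PCA in the gene-embedding orientation: with \eqn{X} the N-gene by
#' M-sample matrix, the k-th PC score vector \eqn{u_k} (one coordinate per
#' gene) is the k-th eigenvector of the Gram matrix \eqn{X X^T}
#' (\eqn{X X^T u_k = \lambda_k u_k}), and the k-th PC loading vector
#' \eqn{v_k = X^T u_k} (one coordinate per time point) is the corresponding
#' eigenvector of \eqn{X^T X}, with \eqn{\|v_k\| = \sqrt{\lambda_k}}.
#'
#' The decomposition is computed through the thin singular-value decomposition
#' of \eqn{X} (identical math; the N-by-N Gram matrix is never formed).
#' Eigenvector signs are fixed deterministically: each component is flipped so
#' that its largest-magnitude loading entry is positive. All downstream
#' statistics (winding numbers, chi-squared scores) are sign-invariant.
#'
#' @param x a normalized [expression_matrix()], or a bare numeric matrix
#'   (genes in rows) taken as-is at the caller's responsibility.
#' @param k number of components to retain, `2 <= k <= min(N, M)`;
#'   default `min(N, M)` capped at 10. Components beyond the numerical rank
#'   are kept with eigenvalue 0 and flagged in `$degenerate`.
#' @return An object of class `gene_embedding`: list with `scores` (N x k,
#'   orthonormal columns \eqn{u_k}), `loadings` (M x k, \eqn{v_k = X^T u_k}),
#'   `eigenvalues` (descending \eqn{\lambda_k}), `contributions`
#'   (\eqn{\lambda_k} over the total variance across *all* components),
#'   `total_variance`, `degenerate` (logical per component), `gene_ids`,
#'   `time_labels`.
#' @export
#' @examples
#' X <- matrix(c(2, -2, 0, 0, 0, 0, 1, -1), 4, 2)
#' e <- embed_genes(X, k = 2)
#' e$eigenvalues        # 8, 2
#' e$contributions      # 0.8, 0.2
embed_genes <- function(x, k = NULL) {
  if (inherits(x, "expression_matrix")) {
    if (!x$normalized)
      stop("expression_matrix is not normalized; run normalize_samples() first ",
           "(or pass a bare matrix to embed as-is)")
    vals <- x$values
    gene_ids <- x$gene_ids
    time_labels <- x$time_labels
  } else {
    vals <- as.matrix(x)
    gene_ids <- rownames(vals)
    time_labels <- colnames(vals)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(vals)))
    if (is.null(time_labels)) time_labels <- as.character(seq_len(ncol(vals)))
  }
  n <- nrow(vals); m <- ncol(vals)
  r_max <- min(n, m)
  if (is.null(k)) k <- min(r_max, 10L)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > r_max) stop("k (", k, ") exceeds min(N, M) = ", r_max)

  sv <- svd(vals, nu = k, nv = 0)
  d <- sv$d                      # all min(N, M) singular values
  lambda <- d[seq_len(k)]^2
  total <- sum(d^2)
  if (total <= 0) stop("all-zero expression matrix: no variance to decompose")

  scores <- sv$u
  loadings <- crossprod(vals, scores)          # v_k = X^T u_k, norm sqrt(lambda_k)
  # deterministic sign: largest-|.| loading entry positive
  for (j in seq_len(k)) {
    i0 <- which.max(abs(loadings[, j]))
    if (loadings[i0, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  tol <- max(n, m) * .Machine$double.eps * d[1L]
  degenerate <- d[seq_len(k)] <= tol
  dimnames(scores) <- list(gene_ids, paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(time_labels, paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings, eigenvalues = lambda,
                 contributions = lambda / total, total_variance = total,
                 degenerate = degenerate, gene_ids = gene_ids,
                 time_labels = time_labels),
            class = "gene_embedding")
}

#' @export
print.gene_embedding <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat("gene_embedding: ", nrow(x$scores), " genes, ", nrow(x$loadings),
      " time points, ", k, " components\n", sep = "")
  cat("contributions (%):",
      paste(sprintf("%.1f", 100 * x$contributions), collapse = ", "), "\n")
  invisible(x)
}

#' Contribution ratios of the retained components
#'
#' \eqn{\lambda_k / \sum_l \lambda_l}, where the denominator is the total
#' variance over all components (so the retained fractions sum to 1 only when
#' every component is retained). Returned as fractions; multiply by 100 for
#' percent.
#'
#' @param e a [embed_genes()] result.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
contributions <- function(e) {
  stopifnot(inherits(e, "gene_embedding"))
  if (all(e$eigenvalues == 0)) stop("all eigenvalues are zero")
  e$contributions
}

#' Export an embedding as TSV files
#'
#' Writes `<prefix>_scores.tsv` (gene x component), `<prefix>_loadings.tsv`
#' (time point x component) and `<prefix>_eigenvalues.tsv` (component,
#' eigenvalue, contribution).
#'
#' @param e a [embed_genes()] result.
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
write_embedding <- function(e, prefix) {
  stopifnot(inherits(e, "gene_embedding"))
  p1 <- paste0(prefix, "_scores.tsv")
  p2 <- paste0(prefix, "_loadings.tsv")
  p3 <- paste0(prefix, "_eigenvalues.tsv")
  utils::write.table(data.frame(id = e$gene_ids, e$scores, check.names = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(time = e$time_labels, e$loadings, check.names = FALSE),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(component = seq_along(e$eigenvalues),
                                eigenvalue = e$eigenvalues,
                                contribution = e$contributions),
                     p3, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
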