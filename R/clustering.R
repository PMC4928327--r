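#' K-means with best-of-restarts
#'
#' Runs `stats::kmeans` with `restarts` random initializations and keeps the
#' solution with the smallest total within-cluster sum of squares. For 2-D
#' inputs, cluster labels are canonicalized by ascending centroid angle about
#' the overall centroid (so phase clusters are numbered around the cycle);
#' otherwise by first occurrence.
#'
#' @param points numeric n x d matrix (e.g. PC scores of extracted genes).
#' @param k number of clusters, `1 <= k <= n`.
#' @param restarts number of random starts (default 100).
#' @param seed RNG seed.
#' @param gene_ids optional row identifiers.
#' @return Object of class `cluster_assignment`: `gene_ids`, `labels` (in
#'   `1..k`), `method = "kmeans"`, `k`, `objective` (total within-cluster SS),
#'   `centers`.
#' @export
kmeans_best_of <- function(points, k, restarts = 100L, seed = 1L,
                           gene_ids = rownames(points)) {
  points <- as.matrix(points)
  n <- nrow(points)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop("k (", k, ") exceeds the number of points (", n, ")")
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(n))
  set.seed(as.integer(seed))
  km <- stats::kmeans(points, centers = k, nstart = as.integer(restarts),
                      iter.max = 100L)
  perm <- canonical_order(km$centers, points)
  relabel <- match(seq_len(k), perm)
  structure(list(gene_ids = as.character(gene_ids),
                 labels = relabel[km$cluster],
                 method = "kmeans", k = k, objective = km$tot.withinss,
                 centers = km$centers[perm, , drop = FALSE]),
            class = "cluster_assignment")
}

# deterministic cluster numbering: by angle about the grand centroid in 2-D,
# else by first occurrence in the data order
canonical_order <- function(centers, points) {
  k <- nrow(centers)
  if (ncol(centers) == 2L && k > 1L) {
    g <- colMeans(points)
    order(atan2(centers[, 2L] - g[2L], centers[, 1L] - g[1L]))
  } else {
    seq_len(k)
  }
}

#' Gaussian-mixture clustering with BIC model selection
#'
#' Fits Gaussian mixtures over the candidate cluster counts `k_range` through
#' `mclust::Mclust` (default covariance-model alphabet) and returns the hard
#' assignment of the model maximizing BIC in the higher-is-better convention
#' (`2 loglik - params log n`), together with the full BIC trace. Candidates
#' whose fit fails are skipped (NA in the trace).
#'
#' @param points numeric n x d matrix.
#' @param k_range candidate cluster counts (default 1:9).
#' @param seed RNG seed (mixture initialisation).
#' @param gene_ids optional row identifiers.
#' @return Object of class `cluster_assignment` with `method = "gmm"`,
#'   `k` (selected count), `objective` (the BIC trace matrix, candidates x
#'   covariance models), and `model` (selected covariance model name).
#' @importFrom mclust Mclust mclustBIC
#' @export
gmm_bic_select <- function(points, k_range = 1:9, seed = 1L,
                           gene_ids = rownames(points)) {
  points <- as.matrix(points)
  if (length(k_range) < 1L) stop("k_range must be non-empty")
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(points)))
  set.seed(as.integer(seed))
  fit <- Mclust(points, G = k_range, verbose = FALSE)
  if (is.null(fit)) stop("no Gaussian mixture candidate could be fitted")
  k <- fit$G
  labels <- as.integer(fit$classification)
  perm <- canonical_order(t(fit$parameters$mean), points)
  relabel <- match(seq_len(k), perm)
  structure(list(gene_ids = as.character(gene_ids),
                 labels = relabel[labels],
                 method = "gmm", k = k,
                 objective = unclass(fit$BIC), model = fit$modelName),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment: ", x$method, ", k = ", x$k, ", n = ",
      length(x$labels), "\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Cross-tabulate two cluster assignments
#'
#' Counts co-assignments over the shared genes; rows are the clusters of `b`,
#' columns the clusters of `a`.
#'
#' @param a,b `cluster_assignment` objects over the same gene set.
#' @return Integer contingency table (rows: `b`, columns: `a`).
#' @export
crosstab <- function(a, b) {
  stopifnot(inherits(a, "cluster_assignment"), inherits(b, "cluster_assignment"))
  if (!setequal(a$gene_ids, b$gene_ids) ||
      length(a$gene_ids) != length(b$gene_ids))
    stop("assignments cover different gene sets")
  bi <- match(a$gene_ids, b$gene_ids)
  table(b = b$labels[bi], a = a$labels)
}

#' Export a cluster assignment as TSV
#'
#' @param x a `cluster_assignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(x, path) {
  stopifnot(inherits(x, "cluster_assignment"))
  utils::write.table(data.frame(gene_id = x$gene_ids, cluster = x$labels),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
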