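#' Chi-squared outlier statistic and P-values from PC scores
#'
#' For each gene i, computes \eqn{s_i = \sum_{k \in \Omega} (u_{ki}/\sigma_k)^2}
#' where \eqn{\sigma_k} is the population standard deviation (divisor N, about
#' zero) of the k-th PC score over all genes, and attributes the upper-tail
#' chi-squared probability with \eqn{|\Omega|} degrees of freedom,
#' \eqn{p_i = P[\chi^2_{|\Omega|} > s_i]}, under the working assumption that
#' null PC scores are Gaussian. Score columns from [embed_genes()] have unit
#' norm, so \eqn{\sigma_k = 1/\sqrt{N}} and the statistic equals
#' \eqn{N \sum_{k \in \Omega} u_{ki}^2}; the statistic is invariant under any
#' rescaling of a score column.
#'
#' @param e a [embed_genes()] result.
#' @param omega integer vector of component indices (the set Omega), non-empty.
#' @return data.frame with `gene_id`, `statistic`, `p_raw`.
#' @export
chi2_outlier_pvalues <- function(e, omega) {
  stopifnot(inherits(e, "gene_embedding"))
  omega <- sort(unique(as.integer(omega)))
  if (length(omega) < 1L) stop("omega must contain at least one component")
  if (any(omega < 1L) || any(omega > ncol(e$scores)))
    stop("omega out of range: embedding has ", ncol(e$scores), " components")
  u <- e$scores[, omega, drop = FALSE]
  sigma <- sqrt(colMeans(u^2))   # population sd about zero
  if (any(sigma == 0))
    stop("zero standard deviation of scores on component PC",
         omega[which(sigma == 0)[1L]])
  stat <- rowSums(sweep(u, 2L, sigma, "/")^2)
  data.frame(gene_id = e$gene_ids, statistic = stat,
             p_raw = stats::pchisq(stat, df = length(omega), lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around the standard BH step-up adjustment: P-values are
#' sorted ascending, \eqn{q_r = p_r m / r}, monotonicity is enforced from the
#' largest rank down, values are capped at 1 and returned in the original
#' order.
#'
#' @param p numeric vector of P-values in `[0, 1]`.
#' @return adjusted P-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p)) stop("missing P-values")
  if (any(p < 0 | p > 1)) stop("P-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Extract outlier genes along selected components
#'
#' Composes [chi2_outlier_pvalues()] and [bh_adjust()]; a gene is selected
#' when its adjusted P-value is strictly below `alpha`.
#'
#' @param e a [embed_genes()] result.
#' @param omega component index set Omega.
#' @param alpha significance level for the BH-adjusted P-values (strict `<`).
#' @return Object of class `selection_result`: data.frame `table` with
#'   `gene_id`, `statistic`, `p_raw`, `p_adj`, `selected`, plus attributes
#'   `omega` and `alpha`, and `$genes`, the selected [gene_list()].
#' @export
extract_features <- function(e, omega, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  tab <- chi2_outlier_pvalues(e, omega)
  tab$p_adj <- bh_adjust(tab$p_raw)
  tab$selected <- tab$p_adj < alpha
  omega <- sort(unique(as.integer(omega)))
  structure(list(table = tab, omega = omega, alpha = alpha,
                 genes = gene_list(tab$gene_id[tab$selected],
                                   provenance = paste0("chi2 outliers, omega={",
                                                       paste(omega, collapse = ","),
                                                       "}, alpha=", alpha))),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result: ", sum(x$table$selected), " of ", nrow(x$table),
      " genes selected (omega = {", paste(x$omega, collapse = ","),
      "}, BH-adjusted P < ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Export a selection result as TSV
#'
#' @param x a [extract_features()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Integrate gene selections across experiments by occurrence count
#'
#' Counts, over the union of all identifiers, in how many of the
#' experiment-level selections each gene occurs, and keeps genes with count
#' `>= threshold`.
#'
#' @param selections list of [gene_list()] objects (or plain character
#'   vectors), one per experiment.
#' @param threshold minimum occurrence count (inclusive), at most
#'   `length(selections)`.
#' @return Object of class `integration_result`: `counts` (named integer
#'   vector over the union, decreasing), `n_experiments`, `threshold`,
#'   `genes` (the selected [gene_list()]).
#' @export
#' @examples
#' integrate_counts(list(c("a", "b"), c("a", "c")), threshold = 2)$genes
integrate_counts <- function(selections, threshold) {
  if (length(selections) < 1L) stop("need at least one selection")
  threshold <- as.integer(threshold)
  if (threshold < 0L) stop("threshold must be nonnegative")
  if (threshold > length(selections))
    stop("threshold (", threshold, ") exceeds the number of experiments (",
         length(selections), ")")
  ids <- lapply(selections, function(s) {
    if (inherits(s, "gene_list")) s$gene_ids else unique(as.character(s))
  })
  tab <- sort(table(unlist(ids)), decreasing = TRUE)
  counts <- stats::setNames(as.integer(tab), names(tab))
  keep <- names(counts)[counts >= threshold]
  structure(list(counts = counts, n_experiments = length(selections),
                 threshold = threshold,
                 genes = gene_list(keep, provenance = paste0("count >= ", threshold,
                                                             " of ", length(selections)))),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat("integration_result: ", length(x$genes$gene_ids), " genes in >= ",
      x$threshold, " of ", x$n_experiments, " experiments (union ",
      length(x$counts), ")\n", sep = "")
  invisible(x)
}
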