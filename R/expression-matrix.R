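#' Gene-by-time-point expression matrix
#'
#' Lightweight container for a numeric expression matrix with genes in rows
#' and time points (samples) in columns, plus a flag recording whether
#' per-sample normalization has been applied.
#'
#' @param values numeric matrix, genes x time points; no missing values.
#' @param gene_ids character vector of row identifiers (length `nrow(values)`).
#' @param time_labels character vector of column labels (length `ncol(values)`).
#' @param normalized logical; `TRUE` once each column has mean 0 and
#'   population mean square 1 (see [normalize_samples()]).
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `gene_ids`, `time_labels`, `normalized`.
#' @export
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 4, 3), paste0("g", 1:4), paste0("t", 1:3))
#' dim(x)
expression_matrix <- function(values, gene_ids = rownames(values),
                              time_labels = colnames(values),
                              normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(time_labels)) time_labels <- as.character(seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  time_labels <- as.character(time_labels)
  if (length(gene_ids) != nrow(values))
    stop("length of 'gene_ids' (", length(gene_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(time_labels) != ncol(values))
    stop("length of 'time_labels' (", length(time_labels),
         ") != number of columns (", ncol(values), ")")
  if (nrow(values) < 2) stop("need at least 2 genes")
  if (ncol(values) < 3) stop("need at least 3 time points")
  if (anyNA(values)) stop("missing values in expression matrix; drop or impute before construction")
  dimnames(values) <- list(gene_ids, time_labels)
  structure(list(values = values, gene_ids = gene_ids,
                 time_labels = time_labels, normalized = isTRUE(normalized)),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " time points (", if (x$normalized) "normalized" else "raw", ")\n", sep = "")
  invisible(x)
}

#' Ordered gene list with provenance
#'
#' @param gene_ids character vector of unique identifiers.
#' @param provenance free-text label (experiment name, threshold used, ...).
#' @return Object of class `gene_list`.
#' @export
gene_list <- function(gene_ids, provenance = "") {
  gene_ids <- as.character(gene_ids)
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene identifiers: ", paste(utils::head(dup, 5), collapse = ", "))
  structure(list(gene_ids = gene_ids, provenance = as.character(provenance)[1]),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat("gene_list (", length(x$gene_ids), " genes",
      if (nzchar(x$provenance)) paste0("; ", x$provenance), ")\n", sep = "")
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$gene_ids)
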