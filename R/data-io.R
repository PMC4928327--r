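# strsplit drops trailing empty fields; keep them with a sentinel
split_tabs <- function(line) {
  parts <- strsplit(paste0(line, "\t\x01"), "\t", fixed = TRUE)[[1]]
  parts[-length(parts)]
}

#' Read a GEO series-matrix file
#'
#' Parses the series-matrix text dialect: metadata lines start with `"!"`, and
#' the expression table is the tab-separated block between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` markers. The
#' first table row holds sample identifiers (used as time labels unless
#' `!Sample_title` metadata is present, in which case the titles are used),
#' the first column holds row (probe/gene) identifiers. Quoted fields are
#' unquoted. Genes with any empty or missing cell are dropped; the number of
#' dropped rows is reported with a message.
#'
#' @param path path to a series-matrix text file.
#' @return An un-normalized [expression_matrix()].
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("format error: series-matrix table markers ",
         "(!series_matrix_table_begin / !series_matrix_table_end) not found in ", path)

  unquote <- function(x) gsub('^"|"$', "", x)

  # sample titles, if present, become the time labels
  titles <- NULL
  tl <- grep("^!Sample_title\\b", lines[seq_len(beg - 1L)], value = TRUE)
  if (length(tl) == 1L) {
    fields <- unquote(split_tabs(tl))
    if (length(fields) > 1L) titles <- fields[-1L]
  }

  block <- lines[(beg + 1L):(end - 1L)]
  block <- block[nzchar(block)]
  rows <- lapply(block, function(l) unquote(split_tabs(l)))
  header <- rows[[1L]]
  body <- rows[-1L]
  ncol_expect <- length(header)
  bad <- which(vapply(body, length, 1L) != ncol_expect)
  if (length(bad))
    stop("parse error: row ", bad[1L] + 1L, " of the table has ",
         length(body[[bad[1L]]]), " fields, expected ", ncol_expect)

  ids <- vapply(body, `[[`, "", 1L)
  cells <- t(vapply(body, function(r) r[-1L], character(ncol_expect - 1L)))
  trimmed <- array(trimws(cells), dim(cells))
  empty <- array(!nzchar(trimmed) | toupper(trimmed) %in% c("NA", "NULL"),
                 dim(cells))
  drop <- rowSums(empty) > 0L
  if (any(drop)) {
    message("read_series_matrix: dropped ", sum(drop),
            " gene(s) with missing entries")
    ids <- ids[!drop]
    cells <- cells[!drop, , drop = FALSE]
  }
  vals <- suppressWarnings(array(as.numeric(cells), dim(cells)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("parse error: non-numeric cell at gene '", ids[idx[1L]],
         "', sample column ", idx[2L], " ('", cells[idx[1L], idx[2L]], "')")
  }
  labels <- if (!is.null(titles) && length(titles) == ncol(vals)) titles else header[-1L]
  expression_matrix(vals, gene_ids = ids, time_labels = labels, normalized = FALSE)
}

#' Read a plain gene x time-point TSV matrix
#'
#' First row holds time labels, first column holds gene identifiers,
#' tab-delimited. Windows line endings are tolerated.
#'
#' @param path path to the file.
#' @return An un-normalized [expression_matrix()].
#' @export
read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, split_tabs)
  header <- rows[[1L]]
  body <- rows[-1L]
  # header may or may not carry a leading corner label
  nfield <- vapply(body, length, 1L)
  if (length(unique(nfield)) != 1L)
    stop("parse error: ragged rows (", paste(unique(nfield), collapse = ", "),
         " fields) in ", path)
  m <- nfield[1L] - 1L
  labels <- if (length(header) == m) header else header[-1L]
  if (length(labels) != m)
    stop("parse error: header has ", length(header), " fields but rows have ",
         nfield[1L])
  ids <- vapply(body, `[[`, "", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene ID rows: ", paste(dup, collapse = ", "))
  cells <- t(vapply(body, function(r) r[-1L], character(m)))
  vals <- suppressWarnings(array(as.numeric(cells), dim(cells)))
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("parse error: non-numeric cell at gene '", ids[idx[1L]],
         "', column ", idx[2L])
  }
  expression_matrix(vals, gene_ids = ids, time_labels = labels, normalized = FALSE)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_tsv_matrix()]; numbers are written with full precision
#' (15 significant digits) so that read-write-read round-trips reproduce
#' round-trippable decimal text exactly.
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(id = x$gene_ids,
                   format(x$values, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", x$time_labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample normalization
#'
#' Centres every time-point column to mean 0 over genes and scales it so the
#' population mean square equals 1, i.e. \eqn{(1/N)\sum_i x_{ij} = 0} and
#' \eqn{(1/N)\sum_i x_{ij}^2 = 1} with divisor \eqn{N} (number of genes).
#' No row (per-gene) scaling is performed.
#'
#' @param x an un-normalized [expression_matrix()].
#' @return The normalized `expression_matrix` (flag set).
#' @export
#' @examples
#' x <- expression_matrix(matrix(c(1, 3, 0, 2, 4, 6), 2, 3))
#' normalize_samples(x)$values[, 1]  # -1, 1
normalize_samples <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  n <- nrow(v)
  ctr <- sweep(v, 2L, colMeans(v), "-")
  msq <- colMeans(ctr^2)
  if (any(msq <= 0)) {
    j <- which(msq <= 0)[1L]
    stop("zero variance in sample column '", x$time_labels[j], "'")
  }
  out <- sweep(ctr, 2L, sqrt(msq), "/")
  expression_matrix(out, x$gene_ids, x$time_labels, normalized = TRUE)
}

#' Drop time points by index
#'
#' Keeps the time points for which `keep` holds, preserving order. `keep` may
#' be a predicate on the 1-based time index or an integer/logical index
#' vector. If the input was normalized, per-sample normalization is re-applied
#' to the surviving columns.
#'
#' @param x an [expression_matrix()].
#' @param keep function of the integer time index returning logical, or an
#'   index vector.
#' @return The filtered `expression_matrix`.
#' @export
#' @examples
#' x <- expression_matrix(matrix(rnorm(40), 4, 10))
#' dim(mask_time_points(x, function(j) j <= 5))
mask_time_points <- function(x, keep) {
  stopifnot(inherits(x, "expression_matrix"))
  m <- ncol(x$values)
  idx <- seq_len(m)
  sel <- if (is.function(keep)) {
    k <- vapply(idx, function(j) isTRUE(keep(j)), logical(1))
    idx[k]
  } else if (is.logical(keep)) {
    idx[keep]
  } else {
    ii <- as.integer(keep)
    ii[ii >= 1L & ii <= m]
  }
  sel <- sort(unique(sel))
  if (length(sel) < 3L)
    stop("fewer than 3 time points survive the mask (", length(sel), ")")
  out <- expression_matrix(x$values[, sel, drop = FALSE], x$gene_ids,
                           x$time_labels[sel], normalized = FALSE)
  if (x$normalized) out <- normalize_samples(out) else out
}

#' Read / write one-symbol-per-line gene lists
#'
#' @param path file path.
#' @param provenance label attached to the returned list (defaults to the
#'   file name).
#' @return [gene_list()] for `read_gene_list`; `path` invisibly for
#'   `write_gene_list`.
#' @export
read_gene_list <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(sub("\r$", "", ids))
  gene_list(ids[nzchar(ids)], provenance)
}

#' @rdname read_gene_list
#' @param x a [gene_list()].
#' @export
write_gene_list <- function(x, path) {
  stopifnot(inherits(x, "gene_list"))
  writeLines(x$gene_ids, path)
  invisible(path)
}
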