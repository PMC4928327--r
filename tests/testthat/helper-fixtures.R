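# fixtures are built in code at test time; nothing is stored on disk

# minimal series-matrix file; cells is a character matrix (so tests can plant
# empty/invalid cells), ids its row identifiers
write_series_matrix_fixture <- function(path, ids, cells, titles = NULL) {
  n_samp <- ncol(cells)
  lines <- c("!Series_title\t\"toy series\"",
             if (!is.null(titles))
               paste0("!Sample_title\t", paste0('"', titles, '"', collapse = "\t")),
             "!series_matrix_table_begin",
             paste(c("\"ID_REF\"", paste0('"GSM', seq_len(n_samp), '"')),
                   collapse = "\t"),
             vapply(seq_along(ids), function(i)
               paste(c(paste0('"', ids[i], '"'), cells[i, ]), collapse = "\t"), ""),
             "!series_matrix_table_end")
  writeLines(lines, path)
  path
}

write_tsv_fixture <- function(path, ids, values, labels = NULL, eol = "\n") {
  if (is.null(labels)) labels <- paste0("t", seq_len(ncol(values)))
  lines <- c(paste(c("id", labels), collapse = "\t"),
             vapply(seq_along(ids), function(i)
               paste(c(ids[i], format(values[i, ], digits = 15)), collapse = "\t"), ""))
  con <- file(path, "wb")
  writeChar(paste0(paste(lines, collapse = eol), eol), con, eos = NULL)
  close(con)
  path
}

# random per-sample-normalized expression matrix
random_normalized_matrix <- function(n, m, seed) {
  set.seed(seed)
  normalize_samples(expression_matrix(matrix(rnorm(n * m), n, m)))
}

# independent step-up oracle: direct definition of the BH adjustment
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# matrix whose first n_periodic genes follow noisy sin/cos at the given period,
# the rest pure noise; strong amplitude so the periodic genes dominate PC1/PC2
planted_periodic_matrix <- function(n_genes, n_periodic, m, period, seed,
                                    amplitude = 10) {
  set.seed(seed)
  t <- seq_len(m)
  phase <- runif(n_periodic, 0, 2 * pi)
  vals <- matrix(rnorm(n_genes * m, sd = 1), n_genes, m)
  for (i in seq_len(n_periodic))
    vals[i, ] <- amplitude * sin(2 * pi * t / period + phase[i]) +
      rnorm(m, sd = 0.2)
  expression_matrix(vals, gene_ids = c(paste0("per_", seq_len(n_periodic)),
                                       paste0("bg_", seq_len(n_genes - n_periodic))))
}

# R^2 of y on design columns X (intercept added); silent on perfect fits
r_squared <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

# align eigenvector signs between two decompositions before comparing
align_signs <- function(ref, other) {
  for (j in seq_len(ncol(ref)))
    if (sum(ref[, j] * other[, j]) < 0) other[, j] <- -other[, j]
  other
}
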