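#' Generate a synthetic periodic expression data set
#'
#' Builds the benchmark matrix of `n_signal + n_noise` genes by `m` time
#' points. Two basis signals with period 25 are disturbed by periodic uniform
#' noise of amplitude `A` and orthogonalized:
#' \deqn{S^0_j = \sin\{2\pi (j \bmod 25)/25\}, \quad
#'       C^0_j = \cos\{2\pi (j \bmod 25)/25\}}
#' \deqn{S_j = S^0_j + \epsilon^S_{j \bmod 25}, \quad
#'       C^1_j = C^0_j + \epsilon^C_{j \bmod 25}, \quad
#'       C_j = C^1_j - S_j \frac{\sum_j C^1_j S_j}{\sum_j S_j^2}}
#' with \eqn{\epsilon^S, \epsilon^C} each 25 independent draws from
#' \eqn{U[-A, A]} tiled over the grid (so `S` and `C` stay exactly periodic).
#' Signal genes (i = 1..`n_signal`) are \eqn{x^0_{ij} = C_j \cos\delta_i +
#' S_j \sin\delta_i} with phases \eqn{\delta_i \sim U[0, 2\pi]}; noise genes
#' are \eqn{x^0_{ij} \sim U[-1, 1]}. Every gene is finally divided by its
#' population standard deviation over time (divisor `m`, deviations about the
#' per-gene mean; the mean itself is not subtracted).
#'
#' Draw order is fixed (phases, then \eqn{\epsilon^S}, \eqn{\epsilon^C},
#' then the noise-gene matrix) so a seed fully determines the data set.
#'
#' @param A amplitude of the periodic basis disturbance (noise-to-signal
#'   ratio), `>= 0`.
#' @param seed integer RNG seed.
#' @param n_signal,n_noise,m problem size; defaults 100 signal genes, 9900
#'   noise genes, 100 time points (4 periods of 25).
#' @param period basis period in time points (default 25).
#' @return Object of class `synthetic_dataset`: `values`
#'   (`(n_signal+n_noise) x m`), `labels` (logical, `TRUE` = signal),
#'   `A`, `seed`, `basis` (list `S0`, `C0`, `S`, `C`, `eps_S`, `eps_C`),
#'   `phases`, and the size parameters.
#' @export
#' @examples
#' d <- generate_synthetic(A = 1, seed = 1, n_noise = 400)
#' sum(d$labels)                 # 100 signal genes
#' abs(sum(d$basis$C * d$basis$S))  # orthogonal by construction
generate_synthetic <- function(A, seed, n_signal = 100L, n_noise = 9900L,
                               m = 100L, period = 25L) {
  if (!is.numeric(A) || length(A) != 1L || A < 0) stop("A must be >= 0")
  n_signal <- as.integer(n_signal); n_noise <- as.integer(n_noise)
  m <- as.integer(m); period <- as.integer(period)
  if (n_signal < 1L || n_noise < 1L) stop("need signal and noise genes")
  if (m < 3L) stop("need at least 3 time points")
  set.seed(as.integer(seed))

  j <- seq_len(m)
  jm <- j %% period                       # 0 .. period-1
  S0 <- sin(2 * pi * jm / period)
  C0 <- cos(2 * pi * jm / period)

  delta <- stats::runif(n_signal, 0, 2 * pi)
  eps_S <- stats::runif(period, -A, A)
  eps_C <- stats::runif(period, -A, A)
  S <- S0 + eps_S[jm + 1L]
  C1 <- C0 + eps_C[jm + 1L]
  C <- C1 - S * sum(C1 * S) / sum(S^2)    # orthogonalize C against S

  x0 <- rbind(outer(cos(delta), C) + outer(sin(delta), S),
              matrix(stats::runif(n_noise * m, -1, 1), n_noise, m))
  sd_pop <- sqrt(rowMeans(sweep(x0, 1L, rowMeans(x0), "-")^2))
  values <- x0 / sd_pop                   # scale only; mean not subtracted

  n <- n_signal + n_noise
  rownames(values) <- paste0("gene_", seq_len(n))
  colnames(values) <- as.character(j)
  structure(list(values = values,
                 labels = seq_len(n) <= n_signal,
                 A = A, seed = as.integer(seed),
                 basis = list(S0 = S0, C0 = C0, S = S, C = C,
                              eps_S = eps_S, eps_C = eps_C),
                 phases = delta,
                 n_signal = n_signal, n_noise = n_noise, m = m,
                 period = period),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset: ", x$n_signal, " signal + ", x$n_noise,
      " noise genes x ", x$m, " time points, A = ", x$A,
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

# 2x2 confusion matrix: rows = truth (noise, signal), cols = (not selected,
# selected); entries sum to the gene count
confusion_2x2 <- function(labels, selected) {
  matrix(c(sum(!labels & !selected), sum(!labels & selected),
           sum(labels & !selected), sum(labels & selected)),
         2L, 2L, byrow = TRUE,
         dimnames = list(truth = c("noise", "signal"),
                         call = c("not_selected", "selected")))
}

#' Score a synthetic data set with projection-based extraction
#'
#' Embeds the generated matrix as-is (the generator already standardizes per
#' gene), takes Omega = \{1, 2\}, applies the chi-squared outlier statistic
#' with 2 degrees of freedom, BH adjustment, and selects genes at adjusted
#' P < `alpha`.
#'
#' @param d a [generate_synthetic()] data set.
#' @param alpha BH-adjusted significance level (default 0.01).
#' @param normalize also apply per-sample normalization before embedding
#'   (default `FALSE`: the generated matrix is used as-is).
#' @return List: `p_adj`, `selected` (logical per gene), `confusion` (2x2,
#'   rows truth noise/signal, columns not-selected/selected), `accuracy`,
#'   `sensitivity`, `specificity`, `method = "pca"`.
#' @export
score_pca_fe <- function(d, alpha = 0.01, normalize = FALSE) {
  stopifnot(inherits(d, "synthetic_dataset"))
  vals <- d$values
  if (normalize)
    vals <- normalize_samples(expression_matrix(vals))$values
  e <- embed_genes(vals, k = 2L)
  sel <- extract_features(e, omega = 1:2, alpha = alpha)
  selected <- sel$table$selected
  cm <- confusion_2x2(d$labels, selected)
  list(p_adj = sel$table$p_adj, selected = selected, confusion = cm,
       accuracy = (cm[1, 1] + cm[2, 2]) / sum(cm),
       sensitivity = cm[2, 2] / sum(cm[2, ]),
       specificity = cm[1, 1] / sum(cm[1, ]),
       method = "pca")
}

#' Score a synthetic data set with sinusoidal-regression extraction
#'
#' Per-gene OLS of the expression profile on the noise-free sinusoids
#' \eqn{x_{ij} = \alpha_i C^0_j + \beta_i S^0_j + \gamma_i}; the overall
#' F-test P-value is BH-adjusted and genes selected at adjusted P < `alpha`.
#'
#' @inheritParams score_pca_fe
#' @return Same structure as [score_pca_fe()], `method = "regression"`.
#' @export
score_regression_fe <- function(d, alpha = 0.01) {
  stopifnot(inherits(d, "synthetic_dataset"))
  Z <- cbind(C0 = d$basis$C0, S0 = d$basis$S0)
  res <- fit_ols_panel(d$values, Z, "sinusoidal C0/S0")
  p_adj <- bh_adjust(res$p)
  selected <- p_adj < alpha
  cm <- confusion_2x2(d$labels, selected)
  list(p_adj = p_adj, selected = selected, confusion = cm,
       accuracy = (cm[1, 1] + cm[2, 2]) / sum(cm),
       sensitivity = cm[2, 2] / sum(cm[2, ]),
       specificity = cm[1, 1] / sum(cm[1, ]),
       method = "regression")
}

#' Benchmark projection-based vs regression-based extraction
#'
#' For every amplitude in `A_values` and every ensemble, generates a fresh
#' data set (seed = `base_seed + (amplitude index - 1) * ensembles +
#' ensemble index - 1`), scores it with both [score_pca_fe()] and
#' [score_regression_fe()], and averages the 2x2 confusion matrices.
#'
#' @param A_values amplitudes to sweep (default 1:6).
#' @param ensembles independent data sets per amplitude (default 100).
#' @param base_seed integer base seed.
#' @param alpha selection level (default 0.01).
#' @param ... size parameters forwarded to [generate_synthetic()].
#' @return Object of class `benchmark_summary`: data.frame `table` with one
#'   row per (A, method): averaged confusion entries `tn`, `fp`, `fn`, `tp`,
#'   mean `accuracy` and `sensitivity`; plus `ensembles`, `base_seed`,
#'   `alpha`.
#' @export
run_benchmark <- function(A_values = 1:6, ensembles = 100L, base_seed = 1L,
                          alpha = 0.01, ...) {
  ensembles <- as.integer(ensembles)
  if (ensembles < 1L) stop("ensembles must be at least 1")
  if (length(A_values) < 1L || any(A_values < 0)) stop("invalid A values")
  rows <- list()
  for (ia in seq_along(A_values)) {
    acc <- list(pca = matrix(0, 2, 2), regression = matrix(0, 2, 2))
    mean_acc <- c(pca = 0, regression = 0)
    mean_sens <- c(pca = 0, regression = 0)
    for (ie in seq_len(ensembles)) {
      seed <- as.integer(base_seed) + (ia - 1L) * ensembles + (ie - 1L)
      d <- generate_synthetic(A = A_values[ia], seed = seed, ...)
      for (sc in list(score_pca_fe(d, alpha = alpha),
                      score_regression_fe(d, alpha = alpha))) {
        acc[[sc$method]] <- acc[[sc$method]] + sc$confusion
        mean_acc[sc$method] <- mean_acc[sc$method] + sc$accuracy
        mean_sens[sc$method] <- mean_sens[sc$method] + sc$sensitivity
      }
    }
    for (meth in c("pca", "regression")) {
      cm <- acc[[meth]] / ensembles
      rows[[length(rows) + 1L]] <-
        data.frame(A = A_values[ia], method = meth,
                   tn = cm[1, 1], fp = cm[1, 2], fn = cm[2, 1], tp = cm[2, 2],
                   accuracy = mean_acc[meth] / ensembles,
                   sensitivity = mean_sens[meth] / ensembles,
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), ensembles = ensembles,
                 base_seed = as.integer(base_seed), alpha = alpha),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat("benchmark_summary: ", x$ensembles, " ensembles per A, BH-adjusted P < ",
      x$alpha, "\n", sep = "")
  cat(format_benchmark(x), sep = "\n")
  invisible(x)
}

#' Format a benchmark summary as a confusion-matrix text table
#'
#' One block per method; one row per amplitude with the averaged confusion
#' entries (rows of the underlying 2x2: truth noise / signal; columns: not
#' selected / selected).
#'
#' @param x a [run_benchmark()] result.
#' @return character vector of lines.
#' @export
format_benchmark <- function(x) {
  stopifnot(inherits(x, "benchmark_summary"))
  out <- character()
  for (meth in unique(x$table$method)) {
    sub <- x$table[x$table$method == meth, ]
    out <- c(out, paste0(toupper(substring(meth, 1, 1)), substring(meth, 2)),
             sprintf("  %-4s %12s %12s %12s %12s", "A",
                     "noise/kept", "noise/sel", "signal/kept", "signal/sel"))
    for (i in seq_len(nrow(sub)))
      out <- c(out, sprintf("  %-4g %12.2f %12.2f %12.2f %12.2f", sub$A[i],
                            sub$tn[i], sub$fp[i], sub$fn[i], sub$tp[i]))
  }
  out
}

#' Export a benchmark summary as TSV
#'
#' @param x a [run_benchmark()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(x, path) {
  stopifnot(inherits(x, "benchmark_summary"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
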