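#' Periodic regression basis on an integer time grid
#'
#' Builds the two regressor sequences \eqn{f(t_j)} and \eqn{f(t_j + T/4)} on
#' the grid \eqn{t_j = j, j = 1..M}, for a periodic template \eqn{f} with
#' period `T` satisfying the symmetry constraints \eqn{f(t + T) = f(t)},
#' \eqn{f(T/4 - t) = f(T/4 + t)} and \eqn{f(t + T/2) = -f(t)}:
#' \describe{
#'   \item{sin}{\eqn{f(t) = \sin(2\pi t / T)}.}
#'   \item{square}{\eqn{f(t) = \mathrm{sign}(\sin(2\pi t/T))}, with the value
#'     at zero crossings defined as 0 (preserves odd symmetry).}
#'   \item{triangle}{\eqn{f(t) = (2/\pi)\arcsin(\sin(2\pi t/T))}: the
#'     piecewise-linear odd wave in phase with the sine, peaking at
#'     \eqn{f(T/4) = 1}.}
#' }
#' All three have maximum amplitude 1. The quarter-period-shifted copy plays
#' the role of the quadrature component, so the pair captures an arbitrary
#' phase.
#'
#' @param kind `"sin"`, `"square"` or `"triangle"`.
#' @param T period in time-point units (e.g. 12 for a 36-point series spanning
#'   three cycles, 8 for a 16-point series spanning two).
#' @param M grid length (number of time points), at least 3.
#' @return Object of class `periodic_basis`: `kind`, `T`, `t` (grid), `f`
#'   and `f_shift` (the two regressors).
#' @export
#' @examples
#' b <- make_periodic_basis("sin", T = 12, M = 36)
#' b$f[3]   # 1 at the quarter period
make_periodic_basis <- function(kind = c("sin", "square", "triangle"), T, M) {
  kind <- match.arg(kind)
  if (!is.numeric(T) || length(T) != 1L || T <= 0) stop("period T must be positive")
  M <- as.integer(M)
  if (M < 3L) stop("grid length M must be at least 3")
  t <- seq_len(M)
  structure(list(kind = kind, T = T, t = t,
                 f = periodic_wave(kind, t, T),
                 f_shift = periodic_wave(kind, t + T / 4, T)),
            class = "periodic_basis")
}

# f(t) for the three analytic template kinds; zero crossings of the square
# wave are detected on the phase (t mod T/2 == 0), not on sin() round-off
periodic_wave <- function(kind, t, T) {
  switch(kind,
         sin = sin(2 * pi * t / T),
         square = {
           ph <- (t / (T / 2)) %% 1
           s <- sin(2 * pi * t / T)
           ifelse(abs(ph) < 1e-9 | abs(ph - 1) < 1e-9, 0, sign(s))
         },
         triangle = {
           s <- sin(2 * pi * t / T)
           s <- pmin(1, pmax(-1, s))
           (2 / pi) * asin(s)
         },
         stop("unknown basis kind: ", kind))
}

#' @export
print.periodic_basis <- function(x, ...) {
  cat("periodic_basis: ", x$kind, " wave, T = ", x$T, ", M = ", length(x$t),
      "\n", sep = "")
  invisible(x)
}

# shared OLS engine: one QR of the design, applied to every gene at once.
# Returns coefficients, F-statistic of the full model vs intercept-only and
# its P-value. Constant genes (zero total SS) get F = 0, P = 1.
fit_ols_panel <- function(values, regressors, reg_label) {
  n <- nrow(values); m <- ncol(values)
  Z <- cbind(`(Intercept)` = 1, regressors)
  q <- ncol(Z) - 1L
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z))
    stop("collinear regressors in basis '", reg_label, "'")
  if (m - q - 1L < 1L)
    stop("not enough time points (", m, ") for ", q, " regressors")
  coef <- t(qr.coef(qrz, t(values)))
  fitted <- coef %*% t(Z)
  rss <- rowSums((values - fitted)^2)
  tss <- rowSums(sweep(values, 1L, rowMeans(values), "-")^2)
  df2 <- m - q - 1L
  # degenerate cases: constant gene -> F = 0, P = 1; exact fit -> F = Inf, P = 0
  const <- tss <= 1e-12 * (rowSums(values^2) + .Machine$double.xmin)
  exact <- !const & rss <= 1e-14 * tss
  fstat <- numeric(n)
  reg <- !const & !exact
  fstat[reg] <- ((tss[reg] - rss[reg]) / q) / (rss[reg] / df2)
  fstat[exact] <- Inf
  p <- rep(1, n)
  p[reg] <- stats::pf(fstat[reg], q, df2, lower.tail = FALSE)
  p[exact] <- 0
  list(coef = coef, fstat = fstat, p = p, df = c(q, df2))
}

#' Fit every gene to a periodic basis
#'
#' Per-gene ordinary least squares of the expression profile on
#' \eqn{x(t) = C_0 + C_1 f(t) + C_2 f(t + T/4)}. The fit P-value is the
#' overall F-test of the two-regressor model against the intercept-only
#' model (the two coefficients jointly encode amplitude and phase, so a
#' joint test is used rather than per-coefficient tests).
#'
#' @param x an [expression_matrix()] (any normalization state).
#' @param basis a [make_periodic_basis()] result with grid length `ncol(x)`.
#' @return Object of class `periodic_fit`: data.frame `table` with `gene_id`,
#'   coefficients `C0`, `C1`, `C2`, `fstat`, `p`; plus `basis_label` and `df`.
#' @export
fit_periodic <- function(x, basis) {
  stopifnot(inherits(x, "expression_matrix"), inherits(basis, "periodic_basis"))
  if (length(basis$t) != ncol(x$values))
    stop("basis grid length (", length(basis$t), ") != number of time points (",
         ncol(x$values), ")")
  Z <- cbind(f = basis$f, f_shift = basis$f_shift)
  res <- fit_ols_panel(x$values, Z, paste0(basis$kind, " T=", basis$T))
  tab <- data.frame(gene_id = x$gene_ids,
                    C0 = res$coef[, 1L], C1 = res$coef[, 2L], C2 = res$coef[, 3L],
                    fstat = res$fstat, p = res$p, stringsAsFactors = FALSE)
  structure(list(table = tab, basis_label = paste0(basis$kind, " T=", basis$T),
                 df = res$df),
            class = "periodic_fit")
}

#' Fit every gene to selected PC loadings
#'
#' Same regression machinery as [fit_periodic()], with the centred loading
#' columns \eqn{v_{kj} - \langle v_{kj}\rangle_j}, k in `omega`, as
#' regressors. This is the correlation-based comparator to projection-based
#' extraction: it ranks genes by how well the loading shapes fit, not by the
#' size of their projection.
#'
#' @param x an [expression_matrix()] with the same time points as `e`.
#' @param e a [embed_genes()] result.
#' @param omega non-empty set of component indices.
#' @return A `periodic_fit` object; coefficient columns are named `C0`,
#'   `C_PC<k>` for k in `omega`.
#' @export
fit_to_loadings <- function(x, e, omega) {
  stopifnot(inherits(x, "expression_matrix"), inherits(e, "gene_embedding"))
  omega <- sort(unique(as.integer(omega)))
  if (length(omega) < 1L) stop("omega must contain at least one component")
  if (any(omega < 1L) || any(omega > ncol(e$loadings)))
    stop("omega out of range: embedding has ", ncol(e$loadings), " components")
  if (nrow(e$loadings) != ncol(x$values))
    stop("embedding and matrix disagree on the number of time points")
  V <- e$loadings[, omega, drop = FALSE]
  V <- sweep(V, 2L, colMeans(V), "-")
  colnames(V) <- paste0("PC", omega)
  res <- fit_ols_panel(x$values, V, paste0("loadings {",
                                           paste(omega, collapse = ","), "}"))
  coef <- res$coef
  colnames(coef) <- c("C0", paste0("C_PC", omega))
  tab <- data.frame(gene_id = x$gene_ids, coef, fstat = res$fstat, p = res$p,
                    stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(table = tab,
                 basis_label = paste0("loadings {", paste(omega, collapse = ","), "}"),
                 df = res$df),
            class = "periodic_fit")
}

#' @export
print.periodic_fit <- function(x, ...) {
  cat("periodic_fit: ", nrow(x$table), " genes on basis ", x$basis_label,
      " (F df ", x$df[1], ", ", x$df[2], ")\n", sep = "")
  invisible(x)
}

#' Top n genes of a periodic fit
#'
#' Returns the `n` genes with the smallest fit P-value (ties broken by larger
#' F-statistic, then input order), matching the size of a selection from
#' another method so the two gene sets are comparable.
#'
#' @param fit a [fit_periodic()] / [fit_to_loadings()] result.
#' @param n number of genes, `0 <= n <=` number of genes fitted.
#' @return A [gene_list()] in rank order.
#' @export
rank_equal_count <- function(fit, n) {
  stopifnot(inherits(fit, "periodic_fit"))
  n <- as.integer(n)
  if (n < 0L) stop("n must be nonnegative")
  if (n > nrow(fit$table)) stop("n exceeds the number of genes fitted")
  ord <- order(fit$table$p, -fit$table$fstat, seq_len(nrow(fit$table)))
  gene_list(fit$table$gene_id[ord[seq_len(n)]],
            provenance = paste0("top ", n, " by fit P, basis ", fit$basis_label))
}

#' Export fit results as TSV
#'
#' @param fit a `periodic_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "periodic_fit"))
  utils::write.table(fit$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
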