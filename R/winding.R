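#' Winding number of a planar loading trajectory
#'
#' Treats the M rows of `xy` as an ordered trajectory in the plane, centres
#' each coordinate by its time mean, and accumulates the signed rotation about
#' the origin: the step angle from point j to point j+1 is
#' \eqn{\Delta\theta_{j,j+1} = \mathrm{atan2}(v_j \times v_{j+1},
#' v_j \cdot v_{j+1})} (magnitude from the dot product, sign from the planar
#' cross product, so \eqn{|\Delta\theta| \le \pi}), and the winding number is
#' \eqn{W(M') = \sum_{j=1}^{M'} \Delta\theta_{j,j+1} / 2\pi} in turns. For a
#' loading pair tracing a limit cycle, \eqn{|W(M-1)|} approximates the number
#' of oscillation periods the series spans.
#'
#' @param xy numeric M x 2 matrix (M >= 3): a pair of PC-loading trajectories.
#' @param center subtract the time mean of each coordinate first (default
#'   TRUE; the definition requires centred trajectories).
#' @return List of class `winding_number`: `w` (signed turns, \eqn{W(M-1)}),
#'   `step_angles` (length M-1, radians), `partial` (running
#'   \eqn{W(M')} for M' = 1..M-1).
#' @export
#' @examples
#' th <- 2 * pi * (0:7) / 8
#' winding_number(cbind(cos(th), sin(th)), center = FALSE)$w  # 0.875
winding_number <- function(xy, center = TRUE) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("trajectory must have exactly 2 columns")
  m <- nrow(xy)
  if (m < 3L) stop("need at least 3 time points")
  if (anyNA(xy)) stop("missing values in trajectory")
  if (center) xy <- sweep(xy, 2L, colMeans(xy), "-")
  r2 <- rowSums(xy^2)
  if (any(r2 == 0))
    stop("centred trajectory passes through the origin at time index ",
         which(r2 == 0)[1L], "; angle undefined")
  a <- xy[-m, , drop = FALSE]
  b <- xy[-1L, , drop = FALSE]
  dot <- rowSums(a * b)
  cross <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  dtheta <- atan2(cross, dot)
  structure(list(w = sum(dtheta) / (2 * pi), step_angles = dtheta,
                 partial = cumsum(dtheta) / (2 * pi)),
            class = "winding_number")
}

#' @export
print.winding_number <- function(x, ...) {
  cat("winding number W =", format(x$w, digits = 4), "turns over",
      length(x$step_angles), "steps\n")
  invisible(x)
}

#' Winding numbers for all PC-loading pairs
#'
#' Applies [winding_number()] to the centred loading pair \eqn{(v_k, v_{k'})}
#' for every k < k' up to `k_max`. The stored value for (k', k) is the
#' orientation reversal -W(k, k').
#'
#' @param e a [embed_genes()] result with at least `k_max` components.
#' @param k_max rank cap (default 4): pairs beyond the first few components
#'   rarely trace limit cycles.
#' @return Object of class `winding_matrix`: `pair_values` (k_max x k_max,
#'   antisymmetric, NA diagonal), `step_angles` (named list over "k,k'"),
#'   `k_max`.
#' @export
winding_matrix <- function(e, k_max = 4L) {
  stopifnot(inherits(e, "gene_embedding"))
  k_max <- as.integer(k_max)
  if (k_max < 2L) stop("k_max must be at least 2")
  if (ncol(e$loadings) < k_max)
    stop("embedding has ", ncol(e$loadings), " components, need k_max = ", k_max)
  w <- matrix(NA_real_, k_max, k_max,
              dimnames = list(paste0("PC", 1:k_max), paste0("PC", 1:k_max)))
  steps <- list()
  for (k in seq_len(k_max - 1L)) {
    for (kp in (k + 1L):k_max) {
      res <- winding_number(e$loadings[, c(k, kp)], center = TRUE)
      w[k, kp] <- res$w
      w[kp, k] <- -res$w
      steps[[paste(k, kp, sep = ",")]] <- res$step_angles
    }
  }
  structure(list(pair_values = w, step_angles = steps, k_max = k_max),
            class = "winding_matrix")
}

#' @export
print.winding_matrix <- function(x, ...) {
  cat("winding_matrix (k_max =", x$k_max, "), W in turns:\n")
  print(round(x$pair_values, 3))
  invisible(x)
}

#' Select the PC set for feature extraction from winding numbers
#'
#' Either the single pair with the largest \eqn{|W(M-1)|} (`"best_pair"`,
#' ties broken by the lexicographically smallest pair), or the union of all
#' components appearing in any pair with \eqn{|W| \ge} `w_min`
#' (`"threshold"`).
#'
#' @param wm a [winding_matrix()].
#' @param mode `"best_pair"` or `"threshold"`.
#' @param w_min threshold in turns for `"threshold"` mode (default 0.75:
#'   at least three quarters of a rotation over the whole series).
#' @return Sorted integer vector of component indices (the set Omega).
#' @export
select_pc_set <- function(wm, mode = c("best_pair", "threshold"), w_min = 0.75) {
  stopifnot(inherits(wm, "winding_matrix"))
  mode <- match.arg(mode)
  pv <- wm$pair_values
  pairs <- which(upper.tri(pv), arr.ind = TRUE)
  if (nrow(pairs) == 0L) stop("empty winding matrix")
  aw <- abs(pv[pairs])
  if (mode == "best_pair") {
    best <- max(aw)
    cand <- pairs[aw == best, , drop = FALSE]
    ord <- order(cand[, 1L], cand[, 2L])
    sort(as.integer(cand[ord[1L], ]))
  } else {
    keep <- pairs[aw >= w_min, , drop = FALSE]
    if (nrow(keep) == 0L)
      stop("no PC pair reaches |W| >= ", w_min,
           "; no limit cycle detected - supply omega manually")
    sort(unique(as.integer(keep)))
  }
}

#' Export a winding matrix as TSV (k, k', W)
#'
#' @param wm a [winding_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_winding_matrix <- function(wm, path) {
  stopifnot(inherits(wm, "winding_matrix"))
  pairs <- which(upper.tri(wm$pair_values), arr.ind = TRUE)
  df <- data.frame(k = pairs[, 1L], k_prime = pairs[, 2L],
                   W = wm$pair_values[pairs])
  df <- df[order(df$k, df$k_prime), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
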