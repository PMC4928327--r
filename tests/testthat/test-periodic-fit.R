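test_that("analytic bases hit their landmark grid values", {
  s12 <- make_periodic_basis("sin", T = 12, M = 36)
  expect_equal(s12$f[3], 1, tolerance = 1e-12)    # peak at the quarter period
  expect_equal(s12$f[9], -1, tolerance = 1e-12)
  tri8 <- make_periodic_basis("triangle", T = 8, M = 16)
  expect_equal(tri8$f[1], 0.5, tolerance = 1e-12) # halfway up the rise to t = 2
  expect_equal(tri8$f[2], 1, tolerance = 1e-12)
  sq8 <- make_periodic_basis("square", T = 8, M = 16)
  expect_equal(sq8$f[2], 1)
  expect_equal(sq8$f[6], -1)
  expect_equal(sq8$f[4], 0)                       # boundary convention at crossings
  expect_error(make_periodic_basis("saw", T = 8, M = 16), "'arg'")
})

test_that("bases satisfy the periodic symmetry identities on the grid", {
  for (kind in c("sin", "square", "triangle")) {
    for (T in c(8, 12)) {
      M <- 3 * T
      b <- make_periodic_basis(kind, T = T, M = M)
      f <- b$f
      half <- T / 2
      # f(t + T) = f(t); f(t + T/2) = -f(t)
      expect_lt(max(abs(f[seq_len(M - T)] - f[seq_len(M - T) + T])), 1e-10)
      expect_lt(max(abs(f[seq_len(M - half)] + f[seq_len(M - half) + half])), 1e-10)
      # mirror symmetry about the quarter period: f(T/4 - t) = f(T/4 + t)
      q <- T / 4
      for (dt in seq_len(q - 1)) {
        expect_equal(unname(periodic_wave(kind, q - dt, T)),
                     unname(periodic_wave(kind, q + dt, T)), tolerance = 1e-10)
      }
      # amplitude bounded by 1
      expect_lte(max(abs(f)), 1 + 1e-12)
    }
  }
})

test_that("quadrature regressors are orthogonal over whole periods", {
  for (kind in c("sin", "square", "triangle")) {
    b <- make_periodic_basis(kind, T = 12, M = 36)
    expect_lt(abs(sum(b$f * b$f_shift)), 1e-10)
    b2 <- make_periodic_basis(kind, T = 8, M = 16)
    expect_lt(abs(sum(b2$f * b2$f_shift)), 1e-10)
  }
})

test_that("periodic fit recovers planted coefficients exactly", {
  M <- 36
  t <- seq_len(M)
  b <- make_periodic_basis("sin", T = 12, M = M)
  vals <- rbind(3 + 2 * sin(2 * pi * t / 12),   # C0=3, C1=2, C2=0
                rep(1.5, M),                    # constant
                cos(2 * pi * t / 12))           # pure quadrature: C1=0, C2=1
  x <- expression_matrix(vals, gene_ids = c("sin", "const", "cos"))
  fit <- fit_periodic(x, b)
  expect_equal(fit$table$C0[1], 3, tolerance = 1e-10)
  expect_equal(fit$table$C1[1], 2, tolerance = 1e-10)
  expect_equal(fit$table$C2[1], 0, tolerance = 1e-10)
  expect_lt(fit$table$p[1], 1e-15)
  expect_equal(fit$table$fstat[2], 0)
  expect_equal(fit$table$p[2], 1)
  # quarter-period shift identity: cos fits entirely on the shifted regressor
  expect_equal(fit$table$C1[3], 0, tolerance = 1e-10)
  expect_equal(fit$table$C2[3], 1, tolerance = 1e-10)
})

test_that("panel OLS agrees with a direct normal-equations oracle and lm", {
  set.seed(53)
  M <- 24
  b <- make_periodic_basis("triangle", T = 8, M = M)
  vals <- matrix(rnorm(6 * M), 6, M)
  x <- expression_matrix(vals)
  fit <- fit_periodic(x, b)
  Z <- cbind(1, b$f, b$f_shift)
  for (i in 1:6) {
    beta <- solve(crossprod(Z), crossprod(Z, vals[i, ]))  # normal equations
    expect_equal(unname(unlist(fit$table[i, c("C0", "C1", "C2")])),
                 drop(beta), tolerance = 1e-8)
    lmfit <- stats::lm(vals[i, ] ~ b$f + b$f_shift)
    fs <- summary(lmfit)$fstatistic
    expect_equal(fit$table$fstat[i], unname(fs[1]), tolerance = 1e-8)
    expect_equal(fit$table$p[i],
                 unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
                 tolerance = 1e-10)
  }
})

test_that("fitting to PC loadings is exact for loading-shaped genes", {
  x <- random_normalized_matrix(60, 12, seed = 59)
  e <- embed_genes(x, k = 4)
  v2 <- e$loadings[, 2]
  probe <- rbind(v2, v2)                 # genes identical to the PC2 loading
  probe[2, ] <- probe[2, ] + 5           # offset absorbed by the intercept
  px <- expression_matrix(probe, gene_ids = c("v2", "v2_off"))
  fit <- fit_to_loadings(px, e, omega = 2:3)
  expect_lt(fit$table$p[1], 1e-12)
  expect_lt(fit$table$p[2], 1e-12)
  expect_error(fit_to_loadings(px, e, omega = integer(0)), "at least one")
})

test_that("genes orthogonal to the regressors fit with F near 0", {
  set.seed(61)
  x <- random_normalized_matrix(40, 16, seed = 61)
  e <- embed_genes(x, k = 3)
  V <- sweep(e$loadings[, 2:3], 2, colMeans(e$loadings[, 2:3]), "-")
  Z <- cbind(1, V)
  y <- rnorm(16)
  y_orth <- y - Z %*% solve(crossprod(Z), crossprod(Z, y))  # residualize
  px <- expression_matrix(rbind(drop(y_orth), drop(y_orth)))
  fit <- fit_to_loadings(px, e, omega = 2:3)
  expect_lt(fit$table$fstat[1], 1e-10)
  expect_gt(fit$table$p[1], 1 - 1e-6)
})

test_that("equal-count ranking orders by P then F then input order", {
  tab <- data.frame(gene_id = c("a", "b", "c"), C0 = 0, C1 = 0, C2 = 0,
                    fstat = c(1, 50, 4), p = c(0.5, 0.001, 0.2))
  fit <- structure(list(table = tab, basis_label = "toy", df = c(2, 10)),
                   class = "periodic_fit")
  expect_equal(rank_equal_count(fit, 2)$gene_ids, c("b", "c"))
  expect_equal(rank_equal_count(fit, 0)$gene_ids, character(0))
  expect_equal(rank_equal_count(fit, 3)$gene_ids, c("b", "c", "a"))
  expect_error(rank_equal_count(fit, -1), "nonnegative")
  expect_error(rank_equal_count(fit, 4), "exceeds")
  # ties on P break toward the larger F statistic
  tie <- fit
  tie$table$p <- c(0.01, 0.01, 0.5)
  tie$table$fstat <- c(3, 9, 1)
  expect_equal(rank_equal_count(tie, 1)$gene_ids, "b")
})

test_that("collinear regressors are rejected by basis name", {
  M <- 12
  x <- expression_matrix(matrix(rnorm(3 * M), 3, M))
  bad <- structure(list(kind = "sin", T = 6, t = seq_len(M),
                        f = rep(1, M), f_shift = rep(2, M)),
                   class = "periodic_basis")
  expect_error(fit_periodic(x, bad), "collinear")
})
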