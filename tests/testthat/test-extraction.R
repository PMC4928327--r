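test_that("chi-squared statistic matches the df=2 closed form", {
  x <- random_normalized_matrix(200, 8, seed = 13)
  e <- embed_genes(x, k = 4)
  res <- chi2_outlier_pvalues(e, omega = 1:2)
  # closed form at df = 2: p = exp(-s/2)
  expect_equal(res$p_raw, exp(-res$statistic / 2), tolerance = 1e-10)
  # s = 2 ln 20 gives p = 0.05 exactly
  expect_equal(stats::pchisq(2 * log(20), df = 2, lower.tail = FALSE), 0.05,
               tolerance = 1e-12)
  # both statistic forms agree: sum (u/sigma)^2 == N * sum u^2
  u <- e$scores[, 1:2]
  expect_equal(res$statistic, unname(nrow(u) * rowSums(u^2)), tolerance = 1e-8)
})

test_that("chi-squared tails agree with numerical integration for df 1..4", {
  for (df in 1:4) {
    grid <- c(0.5, 1, 2, 5, 10)
    for (s in grid) {
      oracle <- stats::integrate(function(z) stats::dchisq(z, df), s, Inf,
                                 rel.tol = 1e-12)$value
      expect_equal(stats::pchisq(s, df, lower.tail = FALSE), oracle,
                   tolerance = 1e-8)
    }
  }
})

test_that("statistic is invariant under score-column rescaling and zero for null genes", {
  x <- random_normalized_matrix(100, 6, seed = 17)
  e <- embed_genes(x, k = 3)
  base <- chi2_outlier_pvalues(e, 1:2)
  e10 <- e
  e10$scores[, 1] <- e10$scores[, 1] * 10
  scaled <- chi2_outlier_pvalues(e10, 1:2)
  expect_equal(scaled$statistic, base$statistic, tolerance = 1e-10)
  expect_equal(scaled$p_raw, base$p_raw, tolerance = 1e-10)
  # a gene with zero scores on omega has statistic 0 and p = 1
  e0 <- e
  e0$scores[1, 1:2] <- 0
  res0 <- chi2_outlier_pvalues(e0, 1:2)
  expect_equal(res0$statistic[1], 0)
  expect_equal(res0$p_raw[1], 1)
})

test_that("BH adjustment reproduces hand-worked and brute-force values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.5, 1e-4)), c(0.5, 2e-4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # brute-force step-up oracle on random vectors of length <= 8
  set.seed(29)
  for (rep in 1:25) {
    p <- round(runif(sample(1:8, 1)), 3)  # rounding provokes ties
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("adjusted P-values dominate raw ones and respect the ordering", {
  set.seed(31)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))
})

test_that("a planted outlier is selected among null genes", {
  # one gene 10 sigma out on each of 2 PCs among 1000 nulls
  set.seed(37)
  n <- 1000
  scores <- cbind(rnorm(n), rnorm(n))
  scores[1, ] <- c(10 * stats::sd(scores[-1, 1]), 10 * stats::sd(scores[-1, 2]))
  scores <- sweep(scores, 2, sqrt(colSums(scores^2)), "/")  # unit columns
  e <- structure(list(scores = scores, loadings = matrix(0, 3, 2),
                      eigenvalues = c(2, 1), gene_ids = paste0("g", 1:n),
                      time_labels = c("a", "b", "c")), class = "gene_embedding")
  sel <- extract_features(e, omega = 1:2, alpha = 0.01)
  expect_true(sel$table$selected[1])
  expect_equal(sel$genes$gene_ids[1], "g1")
  # statistic about 200: chi2 tail far below any BH cutoff
  expect_gt(sel$table$statistic[1], 100)
  # alpha = 0 selects nothing
  sel0 <- extract_features(e, omega = 1:2, alpha = 0)
  expect_equal(sum(sel0$table$selected), 0L)
})

test_that("degenerate identical scores select nothing", {
  n <- 50
  scores <- matrix(1 / sqrt(n), n, 2)
  e <- structure(list(scores = scores, loadings = matrix(0, 3, 2),
                      eigenvalues = c(1, 1), gene_ids = paste0("g", 1:n),
                      time_labels = c("a", "b", "c")), class = "gene_embedding")
  sel <- extract_features(e, 1:2, alpha = 0.01)
  expect_equal(length(unique(sel$table$p_raw)), 1L)
  expect_equal(sum(sel$table$selected), 0L)
})

test_that("null selections stay near the BH level and ignore gene order", {
  fractions <- sapply(1:5, function(seed) {
    x <- random_normalized_matrix(400, 10, seed = 100 + seed)
    e <- embed_genes(x, k = 2)
    sel <- extract_features(e, 1:2, alpha = 0.05)
    mean(sel$table$selected)
  })
  expect_lte(mean(fractions), 0.05)
  # gene reordering permutes the selection with it
  x <- random_normalized_matrix(200, 8, seed = 41)
  e <- embed_genes(x, k = 2)
  sel <- extract_features(e, 1:2, alpha = 0.2)
  set.seed(43)
  perm <- sample(200)
  ep <- embed_genes(x$values[perm, ], k = 2)
  selp <- extract_features(ep, 1:2, alpha = 0.2)
  expect_equal(selp$table$selected, sel$table$selected[perm])
})

test_that("selection results export as TSV", {
  x <- random_normalized_matrix(30, 6, seed = 3)
  e <- embed_genes(x, k = 2)
  sel <- extract_features(e, 1:2, alpha = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection(sel, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 30L)
  expect_equal(back$p_adj, sel$table$p_adj, tolerance = 1e-6)
})

test_that("integration counts occurrences across experiments", {
  lists <- list(c("g1", "g2", "g3"), c("g1", "g2"), c("g1", "g2"),
                c("g1", "g2"), c("g1", "g2"), c("g1"), c("g4"))
  res <- integrate_counts(lists, threshold = 6)
  expect_equal(res$genes$gene_ids, "g1")          # g1 in 6 of 7
  expect_equal(unname(res$counts["g2"]), 5L)      # g2 in 5 of 7: excluded
  res1 <- integrate_counts(lists, threshold = 1)  # union
  expect_setequal(res1$genes$gene_ids, c("g1", "g2", "g3", "g4"))
  expect_error(integrate_counts(lists, threshold = 8), "exceeds")
  # counts are bounded by the number of experiments
  expect_true(all(res$counts >= 0 & res$counts <= res$n_experiments))
})
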