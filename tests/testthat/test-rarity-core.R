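# Designs with known geometry: u in the column space, w orthogonal to it.
make_design <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X)); X <- sweep(X, 2, sqrt(colMeans(X^2)), "/")
  X
}

test_that("fit_block reproduces the adjusted-R2 and variance formulas at hand-computed values", {
  n <- 100; p <- 10
  X <- make_design(n, p, seed = 61)
  # perfect fit: y equal to one design column
  est1 <- fit_block(X[, 1, drop = FALSE], X[, 1])
  expect_equal(est1$r2, 1, tolerance = 1e-12)
  expect_equal(est1$var_r2, 0, tolerance = 1e-12)
  # y orthogonal to every column: R2 = 0 so adj R2 = 1 - 99/89
  y <- std_vec(residuals(lm.fit(cbind(1, X), rnorm(n))))
  est0 <- fit_block(X, y)
  expect_equal(est0$r2, 0, tolerance = 1e-10)
  expect_equal(est0$adj_r2, 1 - 99 / 89, tolerance = 1e-8)
  # R2 = 0.5 at n = 101, p = 10: Var(R2) = 4050 / 1,060,800
  n2 <- 101
  X2 <- make_design(n2, 10, seed = 62)
  u <- std_vec(X2 %*% rnorm(10))                       # inside the span
  w <- std_vec(residuals(lm.fit(cbind(1, X2), rnorm(n2))))  # orthogonal
  y2 <- u + w                                          # r2 exactly 1/2
  est <- fit_block(X2, y2)
  expect_equal(est$r2, 0.5, tolerance = 1e-10)
  expect_equal(est$var_r2, 4050 / 1060800, tolerance = 1e-8)
  expect_equal(est$var_adj_r2, (100 / 90)^2 * 4050 / 1060800, tolerance = 1e-8)
  # CI symmetric about adj R2; F statistic consistent with pf
  expect_equal(mean(est$ci95), est$adj_r2, tolerance = 1e-12)
  expect_equal(est$f_stat, (0.5 / 10) / (0.5 / 90), tolerance = 1e-8)
  expect_equal(est$p_value, pf(est$f_stat, 10, 90, lower.tail = FALSE))
  expect_lte(est$adj_r2, est$r2)
})

test_that("Algina variance vanishes at R2 in {0,1} and peaks strictly inside", {
  v <- sapply(seq(0, 1, by = 0.01), function(r2)
    4 * r2 * (1 - r2)^2 * 89^2 / ((100^2 - 1) * 103))
  expect_equal(v[1], 0)
  expect_equal(v[101], 0)
  expect_true(which.max(v) > 1 && which.max(v) < 101)
})

test_that("rank-deficient blocks drop dependent columns with a warning", {
  X <- make_design(200, 5, seed = 63)
  Xd <- cbind(X, X[, 1])
  y <- std_vec(rnorm(200))
  expect_warning(est <- fit_block(Xd, y), "dependent")
  expect_equal(est$p_k, 5L)
  expect_error(fit_block(make_design(30, 10, seed = 1)[, rep(1, 29)], rnorm(30)),
               "n - 2")
})

test_that("block-sum heritability is exactly additive with summed variances and a Wald CI", {
  n <- 300
  g <- impute_and_standardize(
    toy_genotypes(random_dosages(n, 40, seed = 64),
                  gene = rep(paste0("G", 1:10), each = 4)))
  bs <- make_gene_blocks(g)
  y <- std_vec(as.numeric(g$dosages %*% rnorm(40, 0, 0.1)) + rnorm(n))
  res <- estimate_h2(bs, y)
  adj <- vapply(res$blocks, `[[`, numeric(1), "adj_r2")
  vadj <- vapply(res$blocks, `[[`, numeric(1), "var_adj_r2")
  expect_identical(res$h2, sum(adj))       # bit-for-bit additivity
  expect_identical(res$var_h2, sum(vadj))
  expect_equal(res$ci95, res$h2 + c(-1, 1) * 1.96 * sqrt(res$var_h2))
  expect_equal(res$K, 10L)
  # matrix input returns one result per column, identical to vector calls
  Y <- cbind(y, std_vec(rnorm(n)))
  res_list <- estimate_h2(bs, Y)
  expect_length(res_list, 2)
  expect_equal(res_list[[1]]$h2, res$h2, tolerance = 1e-12)
  # negative per-block values are retained, never truncated (null phenotype)
  adj_null <- vapply(res_list[[2]]$blocks, `[[`, numeric(1), "adj_r2")
  expect_true(any(adj_null < 0))
})

test_that("gene-level Bonferroni threshold is strict and reported to 3 significant digits", {
  blocks <- list(
    rarity:::block_estimate("A", 3L, 0.05, 500),
    rarity:::block_estimate("B", 3L, 0.001, 500)
  )
  tab <- gene_significance(blocks, n_genes = 18214)
  expect_equal(attr(tab, "threshold"), 2.75e-6)
  expect_false(any(is.na(tab$p_value)))
  # boundary: p exactly at the threshold is not significant
  tab2 <- gene_significance(list(structure(
    list(label = "C", p_k = 1L, adj_r2 = 0, p_value = 2.75e-6),
    class = "block_estimate")), n_genes = 18214)
  expect_false(tab2$significant)
  expect_equal(attr(gene_significance(blocks, n_genes = 1), "threshold"), 0.05)
  expect_error(gene_significance(blocks, n_genes = 0), "positive")
})

test_that("stratum comparison uses a two-sample z on disjoint samples", {
  blocks_a <- list(rarity:::block_estimate("A", 5L, 0.10, 1000))
  a <- rarity:::heritability_result(blocks_a, 1000, "gene", paste0("M", 1:1000))
  b <- rarity:::heritability_result(blocks_a, 1000, "gene", paste0("F", 1:1000))
  cmp0 <- compare_estimates(a, b)
  expect_equal(cmp0$z, 0)
  expect_equal(cmp0$p_value, 1)
  # a difference of 1.96 combined SEs gives p ~ 0.05
  blocks_c <- list(rarity:::block_estimate("A", 5L, 0.10, 1000))
  c2 <- rarity:::heritability_result(blocks_c, 1000, "gene", paste0("F", 1:1000))
  c2$h2 <- a$h2 + 1.96 * sqrt(a$var_h2 + c2$var_h2)
  expect_equal(compare_estimates(c2, a)$p_value, 0.05, tolerance = 1e-3)
  bad <- rarity:::heritability_result(blocks_a, 1000, "gene",
                                      c(paste0("M", 1:999), "F1"))
  expect_error(compare_estimates(a, bad), "disjoint")
})
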