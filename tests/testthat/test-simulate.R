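test_that("genotype generation is reproducible and respects the MAC floor", {
  cfg <- sim_config(n = 400, m = 60, n_genes = 15, seed = 71)
  g1 <- generate_genotypes(cfg)
  g2 <- generate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)   # byte-identical under one seed
  expect_identical(g1$state, "standardized")
  raw <- sweep(sweep(g1$dosages, 2, g1$col_sds, "*"), 2, g1$col_means, "+")
  mac <- pmin(colSums(raw), 2 * 400 - colSums(raw))
  expect_true(all(round(mac) > 2))
  expect_true(all(g1$variants$sim_maf <= 0.01))   # generator parameter range
  expect_equal(length(unique(g1$variants$gene)), 15)
  # independent model: pairwise correlations consistent with the null
  C <- crossprod(g1$dosages) / 400
  off <- abs(C[upper.tri(C)])
  expect_lt(mean(off), 3 / sqrt(400))
  expect_error(generate_genotypes(sim_config(n = 100, m = 5,
                                             maf_range = c(0.001, 0.01))),
               "MAC")
})

test_that("long-range coupling realizes the configured cross-block correlation", {
  cfg <- sim_config(n = 1500, m = 200, n_genes = 40, seed = 72,
                    ld_model = list(type = "long_range", r = 0.5, distance = 1e7))
  g <- generate_genotypes(cfg)
  r2 <- diag(crossprod(g$dosages[, 1:100], g$dosages[, 101:200]) / 1500)^2
  expect_equal(mean(r2), 0.25, tolerance = 0.12)
  # coupled pairs sit at the configured genomic distance
  expect_equal(g$variants$pos[101] - g$variants$pos[1], 1e7, tolerance = 1e5)
})

test_that("simulated phenotypes realize the planted heritability exactly", {
  cfg <- sim_config(n = 500, m = 100, n_genes = 20, true_h2 = 0.3,
                    frac_causal_genes = 0.25, frac_causal_variants = 0.5,
                    seed = 73)
  g <- generate_genotypes(cfg)
  sim <- simulate_phenotype(g, cfg, n_reps = 3)
  # rescaling contract: realized genetic variance equals true_h2
  expect_equal(mean(sim$genetic^2), 0.3, tolerance = 1e-10)
  expect_equal(dim(sim$y), c(500L, 3L))
  expect_lt(max(abs(colMeans(sim$y))), 1e-8)
  expect_lt(max(abs(colMeans(sim$y^2) - 1)), 1e-8)
  # causal variants live inside the selected causal genes
  causal_genes <- unique(g$variants$gene[sim$causal])
  expect_lte(length(causal_genes), ceiling(0.25 * 20))
  expect_equal(length(sim$causal), round(0.5 * sum(g$variants$gene %in% causal_genes)))
  # single causal variant: rescaling is exact too
  cfg1 <- sim_config(n = 500, m = 100, n_genes = 100, true_h2 = 0.1,
                     frac_causal_genes = 0.01, frac_causal_variants = 1,
                     seed = 74)
  sim1 <- simulate_phenotype(g, cfg1)
  expect_length(unique(g$variants$gene[sim1$causal]), 1L)
  expect_equal(mean(sim1$genetic^2), 0.1, tolerance = 1e-10)
  # null heritability: genetic component is identically zero
  cfg0 <- sim_config(n = 500, m = 100, n_genes = 20, true_h2 = 0, seed = 75)
  sim0 <- simulate_phenotype(g, cfg0)
  expect_true(all(sim0$genetic == 0))
})

test_that("calibration table reports per-scenario bias of the block-sum estimator", {
  cfg <- sim_config(n = 600, m = 240, n_genes = 60, true_h2 = 0.1, seed = 76)
  g <- generate_genotypes(cfg)
  tab <- run_calibration(g, list(stringent = prune_preset("rv_default")),
                         cfg, target_size = 60, n_reps = 8)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$bias, tab$mean_h2 - 0.1)
  expect_equal(tab$mc_se, tab$sd_h2 / sqrt(8))
  expect_true(tab$m_retained <= 240)
})

test_that("noncentral-F power is calibrated under the null and monotone in n and h2", {
  # type-I calibration: at h2 ~ 0 the rejection rate is alpha
  g0 <- power_grid(3000, 1e-12, n_sims = 2000, block_sizes = rep(100, 5))
  p0 <- estimate_power(g0, seed = 81)
  expect_lt(abs(p0$power - 0.05), 2 * sqrt(0.05 * 0.95 / 2000))
  # monotone non-decreasing in n and h2 up to Monte Carlo noise
  gr <- power_grid(c(2000, 8000, 30000), c(0.01, 0.05), n_sims = 1500,
                   block_sizes = rep(100, 5))
  tab <- estimate_power(gr, seed = 82)
  for (h2 in c(0.01, 0.05)) {
    pw <- tab$power[tab$h2 == h2][order(tab$n[tab$h2 == h2])]
    expect_true(all(diff(pw) > -0.05))
  }
  for (n in unique(tab$n)) {
    pw <- tab$power[tab$n == n][order(tab$h2[tab$n == n])]
    expect_true(all(diff(pw) > -0.05))
  }
  expect_error(power_grid(90, 0.05, n_sims = 100, block_sizes = rep(100, 5)),
               "exceed")
  expect_error(power_grid(1000, 0.05, n_sims = 10, block_sizes = 100))
})

test_that("F-shortcut power matches direct genotype simulation", {
  n <- 2000; K <- 4; p <- 200; h2 <- 0.03
  cfg <- sim_config(n = n, m = K * p, n_genes = K * p %/% 4, true_h2 = h2,
                    seed = 83)
  g <- generate_genotypes(cfg)
  bs <- make_exome_blocks(g, target_size = p)
  nrep <- 400
  sim <- simulate_phenotype(g, cfg, n_reps = nrep)
  res <- estimate_h2(bs, sim$y)
  h2s <- vapply(res, `[[`, numeric(1), "h2")
  pvals <- 1 - pnorm(h2s / sd(h2s))
  pw_direct <- mean(pvals < 0.05)
  pg <- power_grid(n, h2, n_sims = 4000, block_sizes = rep(p, K))
  pw_f <- estimate_power(pg, seed = 84)$power
  se <- sqrt(pw_direct * (1 - pw_direct) / nrep + pw_f * (1 - pw_f) / 4000)
  expect_lt(abs(pw_direct - pw_f), 3 * max(se, 0.02))
})
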