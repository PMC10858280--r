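test_that("VCF genotypes are coded additively, with presence/absence collapse of multi-allelic records", {
  path <- write_test_vcf(c(
    vcf_record("chr1", 100, "rs1", "A", "G", c("0/0", "0/1", "1/1")),
    vcf_record("chr1", 200, "rs2", "A", "G,T", c("1/2", "0/2", "0/0")),
    vcf_record("chr1", 300, "rs3", "A", "G", c("./.", "0/1", "0|0"))
  ))
  g <- load_genotypes(path, "vcf")
  expect_s3_class(g, "genotype_matrix")
  expect_identical(g$state, "raw")
  expect_equal(unname(g$dosages[, "rs1"]), c(0, 1, 2))
  # het for two different alternates counts once
  expect_equal(unname(g$dosages[, "rs2"]), c(1, 1, 0))
  expect_true(is.na(g$dosages[1, "rs3"]))
  expect_equal(unname(g$dosages[2:3, "rs3"]), c(1, 0))
})

test_that("dosage TSV with sidecar metadata round-trips", {
  dos <- random_dosages(12, 4, seed = 3)
  rownames(dos) <- paste0("S", 1:12)
  colnames(dos) <- paste0("v", 1:4)
  variants <- data.frame(vid = paste0("v", 1:4), chrom = "chr2",
                         pos = c(10, 20, 30, 40),
                         gene = c("A", "A", "B", "B"),
                         cadd = c(10, 20, 30, 40), maf_nfe = 0.001)
  f <- write_test_tsv(dos, variants)
  g <- load_genotypes(f$tsv, "tsv", meta_path = f$meta)
  expect_equal(dim(g$dosages), c(12, 4))
  expect_equal(g$variants$gene, c("A", "A", "B", "B"))
  expect_equal(g$variants$pos, c(10, 20, 30, 40))
  expect_equal(unname(g$dosages[, "v3"]), unname(dos[, "v3"]))
  expect_error(load_genotypes(tempfile(), "tsv"), "cannot read")
})

test_that("exact HWE test matches a brute-force enumeration oracle", {
  # spec example: strong departure is removed far below the usual cut-off
  expect_lt(hwe_exact_test(25, 0, 75), 5e-6)
  set.seed(42)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    na <- sample(1:n, 1)
    hets <- seq(na %% 2, na, by = 2)
    h <- sample(hets, 1)
    naa <- (na - h) / 2
    expect_equal(hwe_exact_test(naa, h, n - naa - h),
                 oracle_hwe_p(naa, h, n - naa - h), tolerance = 1e-9)
  }
  expect_equal(hwe_exact_test(0, 0, 30), 1)  # monomorphic: nothing to test
})

test_that("qc_filter applies the variant filters in order and reconciles its report", {
  n <- 100
  dos <- random_dosages(n, 6, maf = 0.3, seed = 7)
  dos[, 1] <- 0                                   # monomorphic
  dos[1:11, 2] <- NA                              # 11% missing
  dos[, 3] <- c(rep(2, 25), rep(0, 75))           # extreme HWE departure
  dos[, 4] <- c(1, 1, rep(0, n - 2))              # MAC = 2 (not > 2)
  rownames(dos) <- paste0("S", 1:n)
  g <- toy_genotypes(dos)
  res <- qc_filter(g)
  rep <- res$report
  expect_equal(rep$n_monomorphic_removed, 1L)
  expect_equal(rep$n_missingness_removed, 1L)
  expect_equal(rep$n_hwe_removed, 1L)
  expect_equal(rep$n_mac_removed, 1L)
  expect_equal(rep$n_retained, 2L)
  # counts reconcile exactly
  expect_equal(rep$n_input - rep$n_retained,
               rep$n_monomorphic_removed + rep$n_missingness_removed +
                 rep$n_hwe_removed + rep$n_mac_removed + rep$n_maf_removed)
  expect_equal(n_variants(res$genotypes), 2L)
  # 10% missing exactly is retained (strictly more than 10% is removed)
  dos2 <- random_dosages(n, 1, maf = 0.3, seed = 8)
  dos2[1:10, 1] <- NA
  expect_equal(qc_filter(toy_genotypes(dos2))$report$n_missingness_removed, 0L)
  # idempotence: second pass removes nothing
  res2 <- qc_filter(res$genotypes)
  expect_equal(res2$report$n_retained, res2$report$n_input)
  expect_identical(res2$genotypes$variants$vid, res$genotypes$variants$vid)
  expect_error(qc_filter(impute_and_standardize(res$genotypes)), "raw")
})

test_that("MAF ceiling is strict and applies across reference populations", {
  n <- 1000
  dos <- random_dosages(n, 3, maf = 0.004, seed = 11)
  g <- toy_genotypes(dos)
  g$variants$maf_nfe <- c(0.001, 0.02, 0.001)   # v2 common elsewhere
  g$variants$maf_afr <- c(0.001, 0.001, 0.001)
  res_local <- qc_filter(g, maf_max = 0.01, pop_maf_ceiling = FALSE)
  expect_equal(res_local$report$n_maf_removed, 0L)
  res_pop <- qc_filter(g, maf_max = 0.01, pop_maf_ceiling = TRUE)
  expect_equal(res_pop$report$n_maf_removed, 1L)
  expect_false("v002" %in% res_pop$genotypes$variants$vid)
})

test_that("imputation fills missing entries with column means and standardization is exact", {
  dos <- matrix(c(0, 1, NA, 1,
                  0, 0, 2, 0), ncol = 2)
  rownames(dos) <- paste0("S", 1:4)
  g <- impute_and_standardize(toy_genotypes(dos))
  expect_identical(g$state, "standardized")
  expect_false(anyNA(g$dosages))
  # reconstructed (unstandardized) imputed value is the observed-call mean
  raw <- sweep(sweep(g$dosages, 2, g$col_sds, "*"), 2, g$col_means, "+")
  expect_equal(raw[3, 1], 2 / 3, tolerance = 1e-12)
  expect_equal(raw[, 2], c(0, 0, 2, 0), tolerance = 1e-12,
               ignore_attr = TRUE)  # complete column unchanged by imputation
  expect_lt(max(abs(colMeans(g$dosages))), 1e-8)
  expect_lt(max(abs(colMeans(g$dosages^2) - 1)), 1e-8)
  # zero-variance columns are refused by name
  bad <- toy_genotypes(matrix(c(0, 0, 0, 1, 0, 1), ncol = 2))
  expect_error(impute_and_standardize(bad), "v001")
})
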