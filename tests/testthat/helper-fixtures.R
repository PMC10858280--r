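# Fixtures are built in code at test time; nothing binary is stored.

# Write a small VCF 4.2 file and return its path.
write_test_vcf <- function(records, samples = c("S1", "S2", "S3"),
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# Dosage TSV + sidecar metadata TSV from a matrix and a variant table.
write_test_tsv <- function(dosages, variants,
                           path = tempfile(fileext = ".tsv"),
                           meta_path = tempfile(fileext = ".meta.tsv")) {
  tab <- data.frame(sample_id = rownames(dosages), dosages,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(variants, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(tsv = path, meta = meta_path)
}

# Raw genotype_matrix from a dosage matrix with evenly spaced positions.
toy_genotypes <- function(dosages, chrom = "chr1", spacing = 1000,
                          gene = NULL, pos = NULL, vid = NULL) {
  m <- ncol(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("S", seq_len(nrow(dosages)))
  variants <- data.frame(
    vid = if (is.null(vid)) sprintf("v%03d", seq_len(m)) else vid,
    chrom = if (length(chrom) == 1) rep(chrom, m) else chrom,
    pos = if (is.null(pos)) seq_len(m) * spacing else pos,
    stringsAsFactors = FALSE
  )
  if (!is.null(gene)) variants$gene <- gene
  genotype_matrix(dosages, variants, state = "raw")
}

# Random raw dosage matrix with every column polymorphic and MAC > 2.
random_dosages <- function(n, m, maf = 0.2, seed = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, maf), n, m)
  for (j in seq_len(m)) {
    while (min(sum(d[, j]), 2 * n - sum(d[, j])) <= 2)
      d[, j] <- rbinom(n, 2, maf)
  }
  d
}

# Independent brute-force HWE oracle: direct log-factorial enumeration of
# the conditional distribution of heterozygote counts given allele counts.
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  if (n_a > n) { tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp; n_a <- 2 * n_aa + n_ab }
  if (n_a == 0) return(1)
  hets <- seq(n_a %% 2, n_a, by = 2)
  lp <- vapply(hets, function(h) {
    haa <- (n_a - h) / 2
    hbb <- n - haa - h
    lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
      h * log(2) + lfactorial(n_a) + lfactorial(2 * n - n_a) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  p_obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Standardize a numeric vector to mean 0, variance 1 (denominator n).
std_vec <- function(y) { y <- y - mean(y); y / sqrt(mean(y^2)) }
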