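#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided p-value for departure from Hardy-Weinberg proportions,
#' computed by summing the probabilities of all heterozygote counts (given
#' the observed allele counts) that are no more probable than the observed
#' one. A chi-square test is invalid for rare variants, where expected
#' homozygote counts are far below 1; the exact conditional distribution is
#' the standard replacement.
#'
#' @param n_aa count of minor-allele homozygotes.
#' @param n_ab count of heterozygotes.
#' @param n_bb count of major-allele homozygotes.
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab          # minor allele count
  if (n_a > n) {                   # ensure 'a' is the minor allele
    tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp
    n_a <- 2 * n_aa + n_ab
  }
  if (n_a == 0) return(1)
  # heterozygote counts share the parity of the minor allele count
  hets <- seq(n_a %% 2, n_a, by = 2)
  # recurrence in the conditional distribution P(het | n_a, n):
  # P(h+2)/P(h) = h_aa * h_bb * 4 / ((h+2)(h+1)) with h_aa=(n_a-h)/2 etc.
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    haa <- (n_a - h) / 2
    hbb <- n - haa - h
    lp[i] <- lp[i - 1] + log(4 * haa * hbb) - log((h + 2) * (h + 1))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(n_ab, hets)]
  # relative slack so exact ties (symmetric configurations) are included
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Variant-level quality control
#'
#' Applies, in order: removal of monomorphic variants, variants with a
#' missing-call fraction above `missingness_max`, variants failing the exact
#' Hardy-Weinberg test at `hwe_alpha`, variants with minor allele count not
#' exceeding `mac_min`, and (when `maf_max` is given) variants whose minor
#' allele frequency is not strictly below `maf_max` in the analysis sample
#' and, when `pop_maf_ceiling` is set, in every reference-population MAF
#' column (`maf_<pop>`) of the variant metadata. MAF and MAC are computed on
#' observed (non-missing) calls.
#'
#' @param g a [genotype_matrix()] in state `"raw"`.
#' @param missingness_max maximum tolerated missing-call fraction (default 0.10).
#' @param hwe_alpha Hardy-Weinberg exact-test significance cut-off
#'   (default 5e-6); variants with p below it are removed.
#' @param mac_min variants are retained only when MAC is strictly greater
#'   than this count (default 2, i.e. singletons and doubletons are dropped).
#' @param maf_max optional strict upper bound on MAF (e.g. 0.01 for rare
#'   variants); `NULL` disables the frequency filter.
#' @param pop_maf_ceiling also require MAF < `maf_max` in every
#'   reference-population column present in the metadata.
#' @return list with elements `genotypes` (filtered matrix, still `"raw"`)
#'   and `report` (a `qc_report` with per-filter removal counts).
#' @export
qc_filter <- function(g, missingness_max = 0.10, hwe_alpha = 5e-6,
                      mac_min = 2, maf_max = NULL, pop_maf_ceiling = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$state != "raw") stop("qc_filter requires a genotype_matrix in state 'raw'")
  m0 <- n_variants(g)
  dos <- g$dosages
  n_obs <- colSums(!is.na(dos))

  keep <- rep(TRUE, m0)
  mono <- apply(dos, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) == 0 || all(x == x[1])
  })
  n_mono <- sum(mono & keep); keep <- keep & !mono

  miss_frac <- colMeans(is.na(dos))
  miss <- miss_frac > missingness_max
  n_miss <- sum(miss & keep); keep <- keep & !miss

  hwe_p <- rep(1, m0)
  for (j in which(keep)) {
    x <- dos[, j]; x <- x[!is.na(x)]
    hwe_p[j] <- hwe_exact_test(sum(x == 2), sum(x == 1), sum(x == 0))
  }
  hwe <- hwe_p < hwe_alpha
  n_hwe <- sum(hwe & keep); keep <- keep & !hwe

  g2 <- recompute_freqs(g)
  mac_fail <- g2$variants$mac <= mac_min
  n_mac <- sum(mac_fail & keep); keep <- keep & !mac_fail

  n_maf <- 0L
  if (!is.null(maf_max)) {
    maf_fail <- g2$variants$maf_local >= maf_max
    if (pop_maf_ceiling) {
      pop_cols <- grep("^maf_(?!local$)", names(g2$variants), perl = TRUE, value = TRUE)
      for (col in pop_cols) {
        v <- g2$variants[[col]]
        maf_fail <- maf_fail | (!is.na(v) & v >= maf_max)
      }
    }
    n_maf <- sum(maf_fail & keep); keep <- keep & !maf_fail
  }

  report <- structure(list(
    n_input = m0,
    n_monomorphic_removed = as.integer(n_mono),
    n_missingness_removed = as.integer(n_miss),
    n_hwe_removed = as.integer(n_hwe),
    n_mac_removed = as.integer(n_mac),
    n_maf_removed = as.integer(n_maf),
    n_retained = as.integer(sum(keep))
  ), class = "qc_report")

  list(genotypes = subset_variants(g2, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("variant QC report\n")
  cat(sprintf("  input variants      %d\n", x$n_input))
  cat(sprintf("  monomorphic removed %d\n", x$n_monomorphic_removed))
  cat(sprintf("  missingness removed %d\n", x$n_missingness_removed))
  cat(sprintf("  HWE removed         %d\n", x$n_hwe_removed))
  cat(sprintf("  MAC removed         %d\n", x$n_mac_removed))
  cat(sprintf("  MAF removed         %d\n", x$n_maf_removed))
  cat(sprintf("  retained            %d\n", x$n_retained))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a `qc_report` from [qc_filter()].
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
write_qc_report <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Mean-impute missing genotypes and standardize columns
#'
#' Missing entries are replaced by the column mean of the observed dosages;
#' each column is then centred and scaled to unit variance (variance computed
#' with denominator n, so the standardization contract |mean| < 1e-8 and
#' |var - 1| < 1e-8 holds exactly). The pre-standardization column means and
#' standard deviations are kept on the object so that unstandardized dosages
#' can be reconstructed (needed for gene-burden collapsing).
#'
#' @param g a [genotype_matrix()] in state `"raw"` or `"imputed"` with no
#'   monomorphic columns (run [qc_filter()] first).
#' @return the matrix in state `"standardized"`.
#' @export
impute_and_standardize <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$state == "standardized") return(g)
  dos <- g$dosages
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    na_idx <- which(is.na(dos), arr.ind = TRUE)
    dos[na_idx] <- mu[na_idx[, 2]]
  }
  n <- nrow(dos)
  cm <- colMeans(dos)
  cv <- colMeans(dos^2) - cm^2          # population variance, denominator n
  if (any(cv <= 0)) {
    bad <- g$variants$vid[which(cv <= 0)[1]]
    stop("zero-variance column after imputation: ", bad,
         " (run qc_filter before standardizing)")
  }
  sds <- sqrt(cv)
  dos <- sweep(dos, 2, cm, "-")
  dos <- sweep(dos, 2, sds, "/")
  g$dosages <- dos
  g$col_means <- cm
  g$col_sds <- sds
  g$state <- "standardized"
  g
}

# Unstandardized (imputed) dosages, reconstructed from stored moments when
# the matrix has already been standardized.
imputed_dosages <- function(g) {
  if (g$state != "standardized") {
    dos <- g$dosages
    if (anyNA(dos)) {
      mu <- colMeans(dos, na.rm = TRUE)
      na_idx <- which(is.na(dos), arr.ind = TRUE)
      dos[na_idx] <- mu[na_idx[, 2]]
    }
    return(dos)
  }
  dos <- sweep(g$dosages, 2, g$col_sds, "*")
  sweep(dos, 2, g$col_means, "+")
}
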