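#' Construct a genotype matrix
#'
#' The central container for the pipeline: an `n` samples by `m` variants
#' dosage matrix with per-variant metadata. Dosages code the number of rare
#' (alternate) alleles carried: 0, 1 or 2, with `NA` for missing calls in the
#' `"raw"` state. After [impute_and_standardize()] the entries are real-valued
#' with every column centred to mean 0 and scaled to variance 1.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#'   Raw entries must be 0, 1, 2 or `NA`.
#' @param variants data.frame of per-variant metadata, one row per column of
#'   `dosages`. Must contain `vid`, `chrom` and `pos` (1-based); optional
#'   columns include `ref`, `alt`, `gene`, `func_class` (one of
#'   `"protein_altering"`, `"lof"`, `"other"`), pathogenicity scores
#'   (`cadd`, `mcap`, `revel`) and reference-population frequencies in
#'   columns named `maf_<pop>`.
#' @param samples character vector of unique sample identifiers; defaults to
#'   the rownames of `dosages`.
#' @param state one of `"raw"`, `"imputed"`, `"standardized"`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants`, `samples` and `state`. Variants are sorted by
#'   `(chrom, pos)`. Local minor allele frequency (`maf_local`) and minor
#'   allele count (`mac`) are computed from the observed (non-missing) calls
#'   and stored in `variants`.
#' @seealso [load_genotypes()], [qc_filter()], [impute_and_standardize()]
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages),
                            state = "raw") {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  state <- match.arg(state, c("raw", "imputed", "standardized"))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!all(c("vid", "chrom", "pos") %in% names(variants)))
    stop("`variants` must contain columns vid, chrom and pos")
  if (nrow(variants) != ncol(dosages))
    stop("nrow(variants) must equal ncol(dosages)")
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (state == "raw") {
    obs <- dosages[!is.na(dosages)]
    if (length(obs) && !all(obs %in% c(0, 1, 2)))
      stop("raw dosages must be 0, 1, 2 or NA")
  }
  ord <- order(variants$chrom, variants$pos, variants$vid)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  rownames(variants) <- NULL
  dimnames(dosages) <- list(samples, variants$vid)

  g <- structure(
    list(dosages = dosages, variants = variants, samples = samples,
         state = state),
    class = "genotype_matrix"
  )
  if (state == "raw") g <- recompute_freqs(g)
  g
}

# Refresh maf_local / mac from observed calls. Minor allele is whichever of
# alt/ref is less frequent, so maf_local is always in [0, 0.5].
recompute_freqs <- function(g) {
  n_obs <- colSums(!is.na(g$dosages))
  alt_count <- colSums(g$dosages, na.rm = TRUE)
  af <- ifelse(n_obs > 0, alt_count / (2 * n_obs), 0)
  maf <- pmin(af, 1 - af)
  mac <- pmin(alt_count, 2 * n_obs - alt_count)
  g$variants$maf_local <- maf
  g$variants$mac <- as.integer(round(mac))
  g
}

n_samples <- function(g) length(g$samples)
n_variants <- function(g) nrow(g$variants)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants [state: %s]\n",
              n_samples(x), n_variants(x), x$state))
  chroms <- unique(x$variants$chrom)
  cat(sprintf("  chromosomes: %s\n", paste(utils::head(chroms, 8), collapse = ", ")))
  if (!is.null(x$variants$gene)) {
    ng <- length(unique(stats::na.omit(x$variants$gene)))
    cat(sprintf("  annotated genes: %d\n", ng))
  }
  invisible(x)
}

#' Read genotypes from VCF or a dosage TSV
#'
#' VCF 4.x files (optionally gzipped) are parsed with vcfR; genotypes are
#' coded additively as the number of rare (alternate) alleles. Multi-allelic
#' records are collapsed to a single bi-allelic presence/absence column: the
#' dosage is the count of the most frequent alternate allele in the genotype,
#' so `1/2` (heterozygous for two different alternates) scores 1 while `1/1`
#' scores 2. Missing calls (`./.`) are preserved as `NA`.
#'
#' The TSV dialect is a tab-separated table whose header row holds variant
#' identifiers; the first column holds sample ids and each subsequent cell a
#' dosage in \{0, 1, 2\} or `NA`. Variant metadata (chromosome, position,
#' gene, functional class, pathogenicity scores, population MAFs) comes from
#' a sidecar TSV keyed by `vid`.
#'
#' @param path path to the genotype file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (inferred from the extension).
#' @param meta_path optional sidecar variant-metadata TSV (required metadata
#'   source for TSV input; merged onto VCF records by `vid` when given).
#' @return A [genotype_matrix()] in state `"raw"`.
#' @export
load_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           meta_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read genotype file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  g <- if (format == "vcf") load_genotypes_vcf(path) else load_genotypes_tsv(path)
  if (!is.null(meta_path)) g <- attach_variant_meta(g, meta_path)
  g
}

load_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  # rows = variants, cols = samples -> dosage matrix samples x variants
  dos <- apply(gt, 1:2, gt_to_dosage)
  dos <- t(dos)
  vid <- fix$ID
  vid[is.na(vid) | vid == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(vid) | vid == "."]
  variants <- data.frame(
    vid = make.unique(vid), chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  genotype_matrix(dos, variants, samples = colnames(gt), state = "raw")
}

# Genotype string -> additive dosage with multi-allelic collapse:
# count of the most frequent alternate allele in the call.
gt_to_dosage <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  a <- suppressWarnings(as.integer(alleles))
  if (anyNA(a)) return(NA_real_)
  alt <- a[a > 0]
  if (length(alt) == 0) return(0)
  max(table(alt))
}

load_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("dosage TSV needs a sample-id column plus variants: ", path)
  samples <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(dos)) {
    bad <- which(!apply(tab[, -1, drop = FALSE], 2, is.numeric))[1]
    stop(sprintf("non-numeric dosage in TSV column '%s'", colnames(dos)[bad]))
  }
  vids <- colnames(dos)
  variants <- data.frame(vid = vids, chrom = "un", pos = seq_along(vids),
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants, samples = samples, state = "raw")
}

attach_variant_meta <- function(g, meta_path) {
  if (!file.exists(meta_path)) stop("cannot read metadata file: ", meta_path)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            na.strings = c("NA", ""), check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!"vid" %in% names(meta)) stop("metadata TSV must have a 'vid' column")
  idx <- match(g$variants$vid, meta$vid)
  if (anyNA(idx)) {
    miss <- g$variants$vid[which(is.na(idx))[1]]
    warning(sprintf("no metadata for %d variant(s), e.g. '%s'",
                    sum(is.na(idx)), miss))
  }
  keep_local <- c("vid", "maf_local", "mac")
  for (col in setdiff(names(meta), keep_local)) {
    g$variants[[col]] <- meta[[col]][idx]
  }
  # metadata may re-declare chrom/pos: re-sort to keep the position invariant
  genotype_matrix(g$dosages, g$variants, samples = g$samples, state = g$state)
}

# Subset a genotype matrix to variant columns `j` (logical or integer).
subset_variants <- function(g, j) {
  g$dosages <- g$dosages[, j, drop = FALSE]
  g$variants <- g$variants[j, , drop = FALSE]
  rownames(g$variants) <- NULL
  if (!is.null(g$col_means)) g$col_means <- g$col_means[j]
  if (!is.null(g$col_sds)) g$col_sds <- g$col_sds[j]
  g
}

# Subset samples (e.g. after medication-based exclusion); frequencies are
# refreshed so downstream MAC/MAF filters see the reduced sample.
subset_samples <- function(g, i) {
  g$dosages <- g$dosages[i, , drop = FALSE]
  g$samples <- rownames(g$dosages)
  if (g$state == "raw") g <- recompute_freqs(g)
  g
}
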