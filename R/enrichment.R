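#' Pathogenicity-score enrichment curve
#'
#' Measures how much of the total rare-variant heritability is captured as
#' increasingly "deleterious" variants are included. Variants are ordered
#' loss-of-function first (LoF prioritized ahead of missense, ordered by
#' genomic position within LoF), then missense by descending pathogenicity
#' score. For each percentile step the top fraction of variants is taken,
#' LD-clumped retaining the higher-scored member of each correlated pair
#' (`clump_by_score`, stringent large-window regime), partitioned into
#' gene-wise blocks, and its block-sum heritability is divided by that of
#' the full (also clumped) set. Under no enrichment the curve tracks the
#' diagonal: the top f fraction of variants explains about f of the
#' heritability.
#'
#' @param g a standardized [genotype_matrix()] with `func_class` and score
#'   annotations in the variant metadata.
#' @param y standardized phenotype ([phenotype_vector()] or numeric vector).
#' @param score_name `"cadd"`, `"mcap"` or `"revel"`.
#' @param maf_ceiling optional strict MAF upper bound applied before the
#'   analysis (`maf_local < maf_ceiling`).
#' @param step_pct percentile step size (default 5).
#' @param clump_params clumping parameters (default: r2 > 0.1 within 50 Mb).
#' @return an `enrichment_curve`: list with `score_name`, `points`
#'   (data.frame of fraction included, heritability proportion, variant
#'   count), `h2_full`, `threshold_marker` (fraction at the score's
#'   recommended binary cut-off: CADD 20, M-CAP 0.025, REVEL 0.5) and
#'   `lof_boundary` (fraction at which the last LoF variant enters).
#' @export
enrichment_curve <- function(g, y, score_name = c("cadd", "mcap", "revel"),
                             maf_ceiling = NULL, step_pct = 5,
                             clump_params = prune_params(
                               0.1, 5e7, mode = "clump_by_score")) {
  score_name <- match.arg(score_name)
  stopifnot(inherits(g, "genotype_matrix"), g$state == "standardized")
  if (inherits(y, "phenotype_vector")) y <- y$y
  if (!is.null(maf_ceiling)) {
    keep <- g$variants$maf_local < maf_ceiling
    if (!any(keep)) stop("no variant below the MAF ceiling")
    g <- subset_variants(g, keep)
  }
  v <- g$variants
  score <- v[[score_name]]
  if (is.null(score)) stop("variant metadata has no '", score_name, "' column")
  is_lof <- !is.null(v$func_class) & v$func_class %in% "lof"
  missense <- !is_lof
  if (mean(is.na(score[missense])) > 0.5)
    stop("'", score_name, "' missing for more than half of the missense variants")

  # LoF ahead of all missense: give LoF an infinite effective score; within
  # LoF the ordering is genomic position (encoded as a tiny score offset).
  eff_score <- ifelse(is_lof, Inf, score)
  eff_score[is.na(eff_score)] <- -Inf
  ord <- order(-eff_score, v$chrom, v$pos)

  m <- n_variants(g)
  fractions <- unique(c(seq(step_pct, 100, by = step_pct) / 100, 1))
  h2_of_subset <- function(cols) {
    sub <- subset_variants(g, sort(cols))
    cl <- ld_prune(sub, clump_params,
                   scores = ifelse(is_lof[sort(cols)], Inf,
                                   ifelse(is.na(score[sort(cols)]), -Inf,
                                          score[sort(cols)])))
    bs <- make_gene_blocks(cl$genotypes)
    estimate_h2(bs, y)$h2
  }
  counts <- pmax(1L, round(fractions * m))
  h2s <- vapply(counts, function(k) h2_of_subset(ord[seq_len(k)]), numeric(1))
  h2_full <- h2s[length(h2s)]

  thresholds <- c(cadd = 20, mcap = 0.025, revel = 0.5)
  thr <- thresholds[[score_name]]
  n_above <- sum(eff_score > thr, na.rm = TRUE)
  structure(list(
    score_name = score_name,
    maf_ceiling = maf_ceiling,
    points = data.frame(fraction = fractions,
                        proportion_h2 = h2s / h2_full,
                        n_variants = counts),
    h2_full = h2_full,
    threshold_marker = n_above / m,
    lof_boundary = sum(is_lof) / m
  ), class = "enrichment_curve")
}

#' @export
print.enrichment_curve <- function(x, ...) {
  cat(sprintf("enrichment curve (%s): %d points, total h2 = %.4f\n",
              x$score_name, nrow(x$points), x$h2_full))
  cat(sprintf("  recommended-threshold fraction = %.2f, LoF boundary = %.2f\n",
              x$threshold_marker, x$lof_boundary))
  invisible(x)
}

#' Regression of gene-level heritability on a gene annotation
#'
#' Simple least-squares of per-gene adjusted R-squared on an annotation
#' such as log gene length or the LOEUF evolutionary-constraint score,
#' reporting the slope, the variance explained and a two-sided p-value.
#'
#' @param gene_h2 data.frame with columns `gene` and `adj_r2` (e.g. from
#'   [gene_significance()] or [as.data.frame.heritability_result()]).
#' @param annotation named numeric vector (names = gene symbols) or a
#'   numeric vector aligned to `gene_h2` rows.
#' @return list with `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n_genes`.
#' @export
annotation_regression <- function(gene_h2, annotation) {
  stopifnot(is.data.frame(gene_h2), all(c("gene", "adj_r2") %in% names(gene_h2)))
  x <- if (!is.null(names(annotation))) {
    annotation[gene_h2$gene]
  } else {
    if (length(annotation) != nrow(gene_h2))
      stop("annotation must be named by gene or aligned to gene_h2 rows")
    annotation
  }
  ok <- stats::complete.cases(x, gene_h2$adj_r2)
  if (sum(ok) < 20)
    stop("annotation_regression needs at least 20 annotated genes (got ",
         sum(ok), ")")
  x <- x[ok]; h2 <- gene_h2$adj_r2[ok]
  if (stats::sd(x) == 0) stop("annotation is constant")
  fit <- stats::lm(h2 ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       n_genes = sum(ok))
}
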