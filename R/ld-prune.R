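#' LD pruning parameters
#'
#' @param r2_max retained pairs must have squared Pearson correlation at or
#'   below this threshold (variants are removed when r2 exceeds it).
#' @param window_bp window size in bases within which pairs are compared.
#' @param step_bp window step in bases (kept for interface compatibility
#'   with the sliding-window convention; the greedy scan enforces the
#'   post-condition for every pair within `window_bp` regardless of step).
#' @param mode `"prune_first"` keeps the lower-position variant of a
#'   violating pair; `"clump_by_score"` keeps the higher-scored variant.
#' @return a `prune_params` list.
#' @export
prune_params <- function(r2_max, window_bp, step_bp = 500,
                         mode = c("prune_first", "clump_by_score")) {
  mode <- match.arg(mode)
  stopifnot(r2_max > 0, r2_max <= 1, window_bp > 0, step_bp > 0)
  if (step_bp > window_bp) stop("step_bp must not exceed window_bp")
  structure(list(r2_max = r2_max, window_bp = window_bp, step_bp = step_bp,
                 mode = mode), class = "prune_params")
}

#' Preset pruning regimes
#'
#' `"rv_default"` is the stringent long-range regime required for rare
#' variants (r2 > 0.1 removed within 50 Mb, step 500 b): rare variants can
#' be correlated at multi-megabase distances, and that long-range LD inflates
#' block-sum heritability unless pruned over a large window.
#' `"cv_default"` and `"combined_default"` use the conventional common-variant
#' regime (r2 > 0.9 within 1 Mb, step 500 b).
#'
#' @param name preset name.
#' @return a [prune_params()] object.
#' @export
prune_preset <- function(name) {
  presets <- list(
    rv_default       = prune_params(0.1, 5e7, 500),
    cv_default       = prune_params(0.9, 1e6, 500),
    combined_default = prune_params(0.9, 1e6, 500)
  )
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Windowed pairwise-r2 LD pruning
#'
#' Greedy deterministic scan: variants are visited in priority order
#' (ascending position in `prune_first` mode, descending score in
#' `clump_by_score` mode, ties broken by position then variant id) and a
#' variant is removed when its squared Pearson correlation with any
#' already-retained variant within `window_bp` on the same chromosome
#' exceeds `r2_max`. The retained set therefore satisfies the post-condition
#' globally: no retained pair within the window violates the threshold.
#' Pruning never crosses chromosome boundaries. Correlations are computed on
#' mean-imputed dosages (equivalently, on the standardized design matrix).
#'
#' @param g a [genotype_matrix()] in state `"imputed"` or `"standardized"`
#'   (a raw matrix without missing calls is accepted and treated as imputed).
#' @param params a [prune_params()] object.
#' @param scores per-variant numeric scores, required in `clump_by_score`
#'   mode (higher = retained preferentially; `Inf` forces retention priority,
#'   used for loss-of-function variants in enrichment analysis).
#' @return list with `genotypes` (pruned matrix) and `removed` (character
#'   vector of removed variant ids).
#' @export
ld_prune <- function(g, params = prune_preset("rv_default"), scores = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(params, "prune_params"))
  if (g$state == "raw" && anyNA(g$dosages))
    stop("ld_prune requires imputed or standardized genotypes")
  if (params$mode == "clump_by_score") {
    if (is.null(scores)) stop("clump_by_score mode requires per-variant scores")
    if (length(scores) != n_variants(g))
      stop("scores must have one value per variant")
  }
  v <- g$variants
  if (any(vapply(split(v$pos, v$chrom), is.unsorted, logical(1))))
    stop("variants must be position-sorted within chromosome")

  X <- if (g$state == "standardized") g$dosages else scale_columns(imputed_dosages(g))
  n <- nrow(X)
  keep <- logical(n_variants(g))

  for (chrom in unique(v$chrom)) {
    idx <- which(v$chrom == chrom)
    pos <- v$pos[idx]
    ord <- if (params$mode == "prune_first") {
      idx[order(pos, v$vid[idx])]
    } else {
      idx[order(-scores[idx], v$pos[idx], v$vid[idx])]
    }
    kept <- integer(0)
    kept_pos <- numeric(0)
    for (j in ord) {
      near <- kept[abs(kept_pos - v$pos[j]) <= params$window_bp]
      if (length(near)) {
        r <- crossprod(X[, near, drop = FALSE], X[, j]) / n
        if (any(r * r > params$r2_max)) next
      }
      kept <- c(kept, j)
      kept_pos <- c(kept_pos, v$pos[j])
    }
    keep[kept] <- TRUE
  }
  list(genotypes = subset_variants(g, keep),
       removed = v$vid[!keep])
}

# Centre and scale columns to mean 0, variance 1 (denominator n).
scale_columns <- function(X) {
  n <- nrow(X)
  cm <- colMeans(X)
  X <- sweep(X, 2, cm, "-")
  sds <- sqrt(colMeans(X^2))
  if (any(sds <= 0)) stop("zero-variance column in correlation computation")
  sweep(X, 2, sds, "/")
}

#' Write removed variant ids, one per line
#'
#' Follows the PLINK `.prune.out` convention.
#' @param removed character vector of removed variant ids.
#' @param path output path.
#' @export
write_prune_out <- function(removed, path) {
  writeLines(removed, path)
  invisible(path)
}
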