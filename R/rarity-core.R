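#' Fit one genotype block by OLS
#'
#' For a standardized n x p_k design G_k and standardized phenotype y, the
#' block heritability estimate is the adjusted R-squared of the no-intercept
#' multiple regression of y on G_k (both are mean-centred, so the intercept
#' is identically zero and the conventional n - p_k - 1 residual degrees of
#' freedom are kept):
#'
#'   R2   = ||fitted||^2 / ||y||^2
#'   adjR2 = 1 - (1 - R2) (n - 1) / (n - p_k - 1)
#'
#' The sampling variance of R2 uses Algina's asymptotic approximation
#'
#'   Var(R2) = 4 R2 (1 - R2)^2 (n - p_k - 1)^2 / ((n^2 - 1)(n + 3))
#'
#' scaled by ((n - 1)/(n - p_k - 1))^2 for the adjusted value, and the 95%
#' confidence interval is the Wald interval adjR2 +/- 1.96 sqrt(Var(adjR2)).
#' Significance of the block comes from the overall regression F-test on the
#' raw R2 with (p_k, n - p_k - 1) degrees of freedom.
#'
#' The solve uses a rank-revealing QR factorization rather than an explicit
#' normal-equation inverse; linearly dependent columns are dropped with a
#' warning and p_k is reduced to the effective rank.
#'
#' @param G standardized design matrix for the block (n x p_k).
#' @param y standardized phenotype (numeric vector, or a
#'   [phenotype_vector()] in state `"standardized"`).
#' @param label block label carried into the result.
#' @return a `block_estimate`: list with `label`, `p_k`, `r2`, `adj_r2`,
#'   `var_r2`, `var_adj_r2`, `ci95`, `f_stat`, `p_value`, `n`.
#' @export
fit_block <- function(G, y, label = "block") {
  if (inherits(y, "phenotype_vector")) {
    if (y$state != "standardized")
      stop("phenotype must be prepared (state 'standardized')")
    y <- y$y
  }
  G <- as.matrix(G)
  n <- nrow(G)
  if (length(y) != n) stop("y must have one value per row of G")
  fit <- block_fit_engine(G, matrix(y, ncol = 1), label = label)
  block_estimate(label, fit$p_k, fit$r2[1], n)
}

# Shared QR engine: factorizes once, projects one or many phenotype columns.
# Returns raw R2 per column and the effective predictor count.
block_fit_engine <- function(G, Y, label = "block") {
  n <- nrow(G)
  p <- ncol(G)
  if (p >= n - 2) stop("block '", label, "': p_k must be below n - 2")
  qrG <- qr(G)
  rank <- qrG$rank
  if (rank < p)
    warning("block '", label, "': ", p - rank,
            " linearly dependent column(s) dropped; effective p_k = ", rank)
  qty <- qr.qty(qrG, Y)
  ss_fit <- colSums(qty[seq_len(rank), , drop = FALSE]^2)
  ss_tot <- colSums(Y^2)
  list(r2 = as.numeric(ss_fit / ss_tot), p_k = rank)
}

# Assemble a block_estimate from a raw R2.
block_estimate <- function(label, p_k, r2, n) {
  adj <- adjusted_r2(r2, n, p_k)
  vr2 <- r2_sampling_variance(r2, n, p_k)
  vadj <- ((n - 1) / (n - p_k - 1))^2 * vr2
  half <- 1.96 * sqrt(vadj)
  fstat <- (r2 / p_k) / ((1 - r2) / (n - p_k - 1))
  pval <- stats::pf(fstat, p_k, n - p_k - 1, lower.tail = FALSE)
  structure(list(
    label = label, p_k = as.integer(p_k), n = as.integer(n),
    r2 = r2, adj_r2 = adj, var_r2 = vr2, var_adj_r2 = vadj,
    ci95 = c(adj - half, adj + half), f_stat = fstat, p_value = pval
  ), class = "block_estimate")
}

adjusted_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

r2_sampling_variance <- function(r2, n, p) {
  4 * r2 * (1 - r2)^2 * (n - p - 1)^2 / ((n^2 - 1) * (n + 3))
}

#' @export
print.block_estimate <- function(x, ...) {
  cat(sprintf(
    "block '%s': p_k = %d, R2 = %.4g, adj R2 = %.4g (95%% CI %.4g, %.4g), F p = %.3g\n",
    x$label, x$p_k, x$r2, x$adj_r2, x$ci95[1], x$ci95[2], x$p_value))
  invisible(x)
}

#' Block-sum heritability estimate
#'
#' Sums per-block adjusted R-squared values over all blocks into the total
#' heritability estimate, with the total sampling variance approximated by
#' the sum of the per-block variances (valid when LD pruning has made blocks
#' approximately uncorrelated) and a Wald 95% confidence interval
#' h2 +/- 1.96 sqrt(Var(h2)). Negative per-block adjusted R-squared values
#' are retained: truncating them would bias the sum upward under the null.
#'
#' Blocks are processed independently, so the result does not depend on
#' evaluation order. When `y` is a matrix (one phenotype per column, e.g.
#' simulated replicates) each block is factorized once and all columns are
#' projected through it, and a list of results is returned.
#'
#' @param blockset a `block_set` from [make_exome_blocks()],
#'   [make_gene_blocks()] or [make_burden_block()].
#' @param y standardized phenotype: a [phenotype_vector()], a numeric
#'   vector, or a numeric matrix with one standardized phenotype per column.
#' @return a `heritability_result` (or a list of them for matrix `y`): list
#'   with `h2`, `var_h2`, `ci95`, `n`, `K`, `construct`, `samples` and
#'   `blocks` (the per-block `block_estimate`s).
#' @export
estimate_h2 <- function(blockset, y) {
  stopifnot(inherits(blockset, "block_set"))
  samples <- blockset$samples
  if (inherits(y, "phenotype_vector")) {
    if (y$state != "standardized")
      stop("phenotype must be prepared (state 'standardized')")
    if (!is.null(y$samples) && !is.null(samples) &&
        !identical(y$samples, samples))
      stop("phenotype sample order does not match the block design")
    y <- y$y
  }
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  if (nrow(Y) != nrow(blockset$design))
    stop("y must have one value per design row")

  K <- length(blockset$blocks)
  R <- ncol(Y)
  r2 <- matrix(NA_real_, K, R)
  p_eff <- integer(K)
  for (k in seq_len(K)) {
    b <- blockset$blocks[[k]]
    fit <- block_fit_engine(blockset$design[, b$columns, drop = FALSE], Y,
                            label = b$label)
    r2[k, ] <- fit$r2
    p_eff[k] <- fit$p_k
  }
  labels <- vapply(blockset$blocks, `[[`, character(1), "label")
  n <- nrow(Y)
  results <- lapply(seq_len(R), function(r) {
    ests <- lapply(seq_len(K), function(k)
      block_estimate(labels[k], p_eff[k], r2[k, r], n))
    heritability_result(ests, n, blockset$construct, samples)
  })
  if (is.matrix(y)) results else results[[1]]
}

heritability_result <- function(block_estimates, n, construct, samples = NULL) {
  h2 <- sum(vapply(block_estimates, `[[`, numeric(1), "adj_r2"))
  var_h2 <- sum(vapply(block_estimates, `[[`, numeric(1), "var_adj_r2"))
  half <- 1.96 * sqrt(var_h2)
  structure(list(
    h2 = h2, var_h2 = var_h2, ci95 = c(h2 - half, h2 + half),
    n = as.integer(n), K = length(block_estimates), construct = construct,
    samples = samples, blocks = block_estimates
  ), class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf(
    "heritability estimate (%s blocks): h2 = %.4f (95%% CI %.4f, %.4f)\n",
    x$construct, x$h2, x$ci95[1], x$ci95[2]))
  cat(sprintf("  n = %d samples, K = %d block(s), Var(h2) = %.3g\n",
              x$n, x$K, x$var_h2))
  invisible(x)
}

#' Per-block results as a data frame
#'
#' @param x a `heritability_result`.
#' @param ... unused.
#' @return data.frame with one row per block (label, p_k, r2, adj_r2,
#'   variances, CI bounds, F statistic and p-value).
#' @export
as.data.frame.heritability_result <- function(x, ...) {
  do.call(rbind, lapply(x$blocks, function(b) data.frame(
    label = b$label, p_k = b$p_k, r2 = b$r2, adj_r2 = b$adj_r2,
    var_r2 = b$var_r2, var_adj_r2 = b$var_adj_r2,
    ci_lo = b$ci95[1], ci_hi = b$ci95[2],
    f_stat = b$f_stat, p_value = b$p_value,
    stringsAsFactors = FALSE
  )))
}

#' Gene-level significance with Bonferroni correction
#'
#' Flags genes whose block F-test p-value falls strictly below the
#' Bonferroni-corrected threshold 0.05 / n_genes.
#'
#' @param result a `heritability_result` built from gene-wise blocks, or a
#'   list of `block_estimate`s.
#' @param n_genes number of genes tested (defaults to the number of blocks);
#'   with 18,214 genes the threshold is 2.75e-6.
#' @param alpha family-wise error rate (default 0.05).
#' @return data.frame with columns `gene`, `p_k`, `adj_r2`, `p_value`,
#'   `significant`; the threshold (reported to 3 significant digits) is in
#'   attribute `"threshold"`.
#' @export
gene_significance <- function(result, n_genes = NULL, alpha = 0.05) {
  blocks <- if (inherits(result, "heritability_result")) result$blocks else result
  if (is.null(n_genes)) n_genes <- length(blocks)
  if (n_genes <= 0) stop("n_genes must be positive")
  threshold <- signif(alpha / n_genes, 3)
  out <- data.frame(
    gene = vapply(blocks, `[[`, character(1), "label"),
    p_k = vapply(blocks, `[[`, integer(1), "p_k"),
    adj_r2 = vapply(blocks, `[[`, numeric(1), "adj_r2"),
    p_value = vapply(blocks, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE
  )
  out$significant <- out$p_value < threshold
  attr(out, "threshold") <- threshold
  out
}

#' Compare heritability estimates between disjoint strata
#'
#' Two-sample z-test on the difference of block-sum estimates from disjoint
#' sample strata (e.g. genetic sexes):
#' z = (h2_a - h2_b) / sqrt(Var_a + Var_b), two-sided normal p-value.
#'
#' @param a,b `heritability_result`s computed on non-overlapping samples.
#' @return list with `z`, `p_value`, `diff` and `se`.
#' @export
compare_estimates <- function(a, b) {
  stopifnot(inherits(a, "heritability_result"),
            inherits(b, "heritability_result"))
  if (!is.null(a$samples) && !is.null(b$samples)) {
    overlap <- intersect(a$samples, b$samples)
    if (length(overlap))
      stop("strata share ", length(overlap),
           " sample(s); estimates must come from disjoint strata")
  }
  se <- sqrt(a$var_h2 + b$var_h2)
  d <- a$h2 - b$h2
  z <- if (se == 0 && d == 0) 0 else d / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), diff = d, se = se)
}
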