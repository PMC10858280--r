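#' Block-set container
#'
#' A block set holds the regression designs consumed by [estimate_h2()]: an
#' ordered list of blocks (each a set of column indices into a shared
#' standardized design matrix) plus the design matrix itself. For the
#' `gene` and `exome` constructs the design columns are the pruned,
#' standardized variant dosages; for the `burden` construct they are
#' standardized per-gene rare-allele burden scores.
#'
#' @keywords internal
new_block_set <- function(blocks, construct, design, samples, extra = list()) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  out <- c(list(blocks = blocks, construct = construct, design = design,
                samples = samples), extra)
  structure(out, class = "block_set")
}

new_block <- function(kind, columns, label, chrom = NA_character_) {
  stopifnot(length(columns) >= 1)
  list(kind = kind, columns = as.integer(columns), label = label,
       chrom = chrom, p_k = length(columns))
}

#' @export
print.block_set <- function(x, ...) {
  p <- vapply(x$blocks, `[[`, integer(1), "p_k")
  cat(sprintf("block_set: %d block(s), construct '%s', %d predictors total\n",
              length(x$blocks), x$construct, sum(p)))
  cat(sprintf("  p_k range: %d - %d; n = %d samples\n",
              min(p), max(p), nrow(x$design)))
  invisible(x)
}

#' Exome-wide blocks of adjacent variants
#'
#' Partitions the pruned variants of each chromosome into consecutive runs
#' of about `target_size` variants. A final remainder block smaller than
#' `max(100, target_size / 10)` is merged into its predecessor, avoiding
#' tiny blocks whose adjusted-R2 sampling variance is unstable. Blocks never
#' span chromosomes, and positional order is preserved.
#'
#' @param g a pruned, standardized [genotype_matrix()].
#' @param target_size variants per block (default 5000, the scale at which
#'   the block OLS stays tractable at biobank sample sizes).
#' @return a `block_set` with `construct = "exome"`.
#' @export
make_exome_blocks <- function(g, target_size = 5000) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$state != "standardized")
    stop("make_exome_blocks requires a standardized genotype_matrix")
  n <- n_samples(g)
  if (target_size >= n - 2)
    stop("target_size must be well below the sample count (p_k < n - 2)")
  min_block <- max(100, target_size / 10)
  blocks <- list()
  for (chrom in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chrom)
    L <- length(idx)
    nb_full <- L %/% target_size
    remainder <- L %% target_size
    if (nb_full == 0L || (remainder > 0 && remainder >= min_block)) {
      nb <- nb_full + 1L            # remainder stands as its own block
    } else {
      nb <- max(1L, nb_full)        # remainder merged into the last block
    }
    starts <- seq(1L, by = target_size, length.out = nb)
    ends <- c(starts[-1] - 1L, L)
    for (b in seq_len(nb)) {
      cols <- idx[starts[b]:ends[b]]
      if (length(cols) >= n - 2)
        stop("block larger than n - 2; increase n or reduce block size")
      blocks[[length(blocks) + 1L]] <-
        new_block("exome", cols, sprintf("%s_block%d", chrom, b), chrom)
    }
  }
  new_block_set(blocks, "exome", g$dosages, g$samples)
}

#' Gene-wise blocks of unaggregated variants
#'
#' One block per distinct gene label, containing all of that gene's
#' variants. Variants without a gene annotation are excluded with a warning.
#' A variant annotated to several genes (comma- or semicolon-separated
#' label) is assigned to each of them, matching the convention that
#' gene-wise totals accept the slight inflation from overlapping genes;
#' a gene whose variants span chromosomes still forms a single block.
#'
#' @param g a pruned, standardized [genotype_matrix()] with gene annotations.
#' @return a `block_set` with `construct = "gene"`, blocks ordered by the
#'   genomic position of each gene's first variant.
#' @export
make_gene_blocks <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (g$state != "standardized")
    stop("make_gene_blocks requires a standardized genotype_matrix")
  gene_lists <- variant_gene_lists(g)
  has_gene <- lengths(gene_lists) > 0
  if (!any(has_gene)) stop("no variant carries a gene annotation")
  if (any(!has_gene))
    warning(sum(!has_gene), " variant(s) without gene annotation excluded")
  map <- data.frame(
    col = rep(seq_along(gene_lists), lengths(gene_lists)),
    gene = unlist(gene_lists), stringsAsFactors = FALSE
  )
  first_pos <- tapply(seq_len(nrow(map)), map$gene, function(i) min(map$col[i]))
  genes <- names(sort(first_pos))
  n <- n_samples(g)
  blocks <- lapply(genes, function(gene) {
    cols <- map$col[map$gene == gene]
    if (length(cols) >= n - 2)
      stop("gene '", gene, "' has p_k >= n - 2; cannot fit")
    chroms <- unique(g$variants$chrom[cols])
    if (length(chroms) > 1)
      message("gene '", gene, "' spans chromosomes ",
              paste(chroms, collapse = ","), "; kept as a single block")
    new_block("gene", cols, gene, chroms[1])
  })
  new_block_set(blocks, "gene", g$dosages, g$samples)
}

variant_gene_lists <- function(g) {
  gene <- g$variants$gene
  if (is.null(gene)) gene <- rep(NA_character_, n_variants(g))
  lapply(gene, function(s) {
    if (is.na(s) || s == "") character(0)
    else trimws(strsplit(s, "[,;]")[[1]])
  })
}

#' Gene-burden block
#'
#' Collapses each gene to a single per-sample burden score: the sum of rare
#' allele counts (unstandardized dosages) over the gene's variants. Burden
#' columns are then standardized and placed in one block whose predictor
#' count equals the number of genes. Genes with zero burden variance (no
#' carriers, or identical burden in every sample) are dropped with a message.
#'
#' @param g a pruned [genotype_matrix()] in state `"imputed"` or
#'   `"standardized"` (unstandardized dosages are reconstructed from the
#'   stored column moments).
#' @return list with `blockset` (a `block_set`, `construct = "burden"`) and
#'   `burden_matrix` (the unstandardized n x genes burden scores).
#' @export
make_burden_block <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  gene_lists <- variant_gene_lists(g)
  has_gene <- lengths(gene_lists) > 0
  if (!any(has_gene)) stop("no variant carries a gene annotation")
  dos <- imputed_dosages(g)
  map <- data.frame(
    col = rep(seq_along(gene_lists), lengths(gene_lists)),
    gene = unlist(gene_lists), stringsAsFactors = FALSE
  )
  first_pos <- tapply(map$col, map$gene, min)
  genes <- names(sort(first_pos))
  burden <- vapply(genes, function(gene) {
    rowSums(dos[, map$col[map$gene == gene], drop = FALSE])
  }, numeric(nrow(dos)))
  colnames(burden) <- genes

  v <- apply(burden, 2, stats::var)
  if (any(v <= 0)) {
    message(sum(v <= 0), " zero-variance burden column(s) dropped: ",
            paste(utils::head(genes[v <= 0], 5), collapse = ", "))
    burden <- burden[, v > 0, drop = FALSE]
  }
  if (ncol(burden) == 0) stop("no gene has a polymorphic burden score")
  if (ncol(burden) >= nrow(burden) - 2)
    stop("number of genes must be well below the sample count")
  design <- scale_columns(burden)
  blocks <- list(new_block("burden", seq_len(ncol(design)), "burden"))
  list(
    blockset = new_block_set(blocks, "burden", design, g$samples),
    burden_matrix = burden
  )
}

#' Serialize a block set to JSON
#'
#' Records, per block: label, kind, chromosome, predictor count and the
#' design column names, so a block construction is fully reproducible.
#'
#' @param bs a `block_set`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @export
write_block_set <- function(bs, path = NULL) {
  cn <- colnames(bs$design)
  rec <- lapply(bs$blocks, function(b) list(
    label = b$label, kind = b$kind, chrom = b$chrom, p_k = b$p_k,
    columns = if (is.null(cn)) b$columns else cn[b$columns]
  ))
  js <- jsonlite::toJSON(list(construct = bs$construct, blocks = rec),
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
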