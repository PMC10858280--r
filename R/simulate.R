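#' Simulation configuration
#'
#' Describes a synthetic rare-variant study: sample size, variant count and
#' frequency range, gene structure, causal architecture, trait heritability
#' and the linkage-disequilibrium model of the genotypes.
#'
#' LD models:
#' * `list(type = "independent")` - variants drawn independently.
#' * `list(type = "block_ld", r = 0.5, width = 10)` - within consecutive
#'   runs of `width` variants, each variant's alleles copy the run's first
#'   variant with probability `r` (pairwise dosage correlation about `r`
#'   against the anchor).
#' * `list(type = "long_range", r = 0.5, distance = 1e7)` - variant j in the
#'   first half of the chromosome is coupled, at allele-copy probability
#'   `r`, to the variant `distance` bases away in the second half. This
#'   emulates long-range LD between distant rare variants: the coupled pairs
#'   fall in different genotype blocks, so without large-window pruning the
#'   block-sum heritability double-counts their shared signal.
#'
#' @param n samples.
#' @param m variants (positions are evenly spaced on one chromosome; under
#'   the long-range model the spacing is `distance / (m/2)` so that coupled
#'   pairs sit exactly `distance` bases apart).
#' @param maf_range `c(lo, hi)` minor allele frequency range; the default
#'   (0.001, 0.01) is the rare-variant regime (MAF < 1%).
#' @param n_genes gene count; variants are split into contiguous
#'   equal-sized genes.
#' @param frac_causal_genes fraction of genes carrying causal variants.
#' @param frac_causal_variants fraction of variants, within causal genes,
#'   that are causal.
#' @param true_h2 trait heritability in [0, 1): the realized sample variance
#'   of the genetic component; noise is drawn with variance 1 - true_h2.
#' @param ld_model list describing the LD model (see above).
#' @param seed integer seed; every quantity the generator produces is
#'   reproducible from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n, m, maf_range = c(0.001, 0.01), n_genes = max(1, m %/% 10),
                       frac_causal_genes = 1, frac_causal_variants = 0.2,
                       true_h2 = 0.05, ld_model = list(type = "independent"),
                       seed = 1L) {
  stopifnot(n > 3, m >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_genes >= 1, n_genes <= m,
            frac_causal_genes > 0, frac_causal_genes <= 1,
            frac_causal_variants > 0, frac_causal_variants <= 1,
            true_h2 >= 0, true_h2 < 1)
  if (!is.list(ld_model) || is.null(ld_model$type) ||
      !ld_model$type %in% c("independent", "block_ld", "long_range"))
    stop("ld_model$type must be 'independent', 'block_ld' or 'long_range'")
  structure(list(
    n = as.integer(n), m = as.integer(m), maf_range = maf_range,
    n_genes = as.integer(n_genes), frac_causal_genes = frac_causal_genes,
    frac_causal_variants = frac_causal_variants, true_h2 = true_h2,
    ld_model = ld_model, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate synthetic rare-variant genotypes
#'
#' Dosages are Binomial(2, MAF_j) with MAF_j ~ Uniform(maf_range); any
#' column with minor allele count of 2 or fewer is redrawn (rare-variant QC
#' retains MAC > 2 only, so qualifying variants must clear that floor).
#' Positions are evenly spaced on one chromosome and variants are annotated
#' to contiguous equal-sized genes, so window- and gene-based operations are
#' well defined. The matrix is returned standardized and fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a standardized [genotype_matrix()].
#' @export
generate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n; m <- cfg$m
  if (2 * n * cfg$maf_range[2] <= 3)
    stop("maf_range upper bound too low to clear the MAC > 2 floor at n = ", n)

  draw_col <- function(maf) {
    for (i in 1:200) {
      x <- stats::rbinom(n, 2, maf)
      mac <- min(sum(x), 2 * n - sum(x))
      if (mac > 2) return(x)
    }
    stop("could not draw a column with MAC > 2 at maf = ", signif(maf, 3),
         "; raise maf_range or n")
  }

  mafs <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  dos <- matrix(0, n, m)
  lm_ <- cfg$ld_model
  if (lm_$type == "independent") {
    for (j in seq_len(m)) dos[, j] <- draw_col(mafs[j])
  } else if (lm_$type == "block_ld") {
    width <- lm_$width %||% 10
    anchors <- seq(1, m, by = width)
    for (a in anchors) {
      dos[, a] <- draw_col(mafs[a])
      for (j in (a + 1):min(a + width - 1, m)) {
        if (j > m || j == a) next
        dos[, j] <- couple_column(dos[, a], mafs[a], lm_$r, n, draw_col)
        mafs[j] <- mafs[a]
      }
    }
  } else { # long_range
    half <- m %/% 2
    if (half < 1) stop("long_range model needs m >= 2")
    for (j in seq_len(half)) dos[, j] <- draw_col(mafs[j])
    for (j in seq_len(m - half)) {
      src <- j
      mafs[half + j] <- mafs[src]
      dos[, half + j] <- couple_column(dos[, src], mafs[src], lm_$r, n, draw_col)
    }
  }

  spacing <- if (lm_$type == "long_range") {
    max(1, round((lm_$distance %||% 1e7) / (m %/% 2)))
  } else 1000
  gene_size <- ceiling(m / cfg$n_genes)
  gene <- paste0("G", ((seq_len(m) - 1) %/% gene_size) + 1)
  variants <- data.frame(
    vid = sprintf("v%05d", seq_len(m)), chrom = "chr1",
    pos = seq_len(m) * spacing, gene = gene,
    func_class = "protein_altering", sim_maf = mafs,
    stringsAsFactors = FALSE
  )
  g <- genotype_matrix(dos, variants, samples = sprintf("S%05d", seq_len(n)),
                       state = "raw")
  impute_and_standardize(g)
}

# Couple a new column to `src`: each of the two allele draws copies the
# corresponding source allele with probability r, otherwise is a fresh
# Bernoulli(maf) draw. Dosage correlation with the source is ~r and the
# marginal MAF is preserved. The MAC floor is enforced by redrawing the
# coupling, and as a last resort an independent column is used.
couple_column <- function(src, maf, r, n, draw_col) {
  stopifnot(r >= 0, r <= 1)
  src1 <- ifelse(src >= 1, 1, 0)          # first allele carrier indicator
  src2 <- ifelse(src == 2, 1, 0)
  for (i in 1:200) {
    keep1 <- stats::rbinom(n, 1, r)
    keep2 <- stats::rbinom(n, 1, r)
    a1 <- ifelse(keep1 == 1, src1, stats::rbinom(n, 1, maf))
    a2 <- ifelse(keep2 == 1, src2, stats::rbinom(n, 1, maf))
    x <- a1 + a2
    mac <- min(sum(x), 2 * n - sum(x))
    if (mac > 2) return(x)
  }
  draw_col(maf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate phenotypes with a planted causal architecture
#'
#' Causal genes are drawn uniformly at random (`frac_causal_genes` of all
#' genes), then causal variants uniformly within them
#' (`frac_causal_variants` of their variants). Effects are standard normal
#' on the standardized genotype scale - independent of allele frequency -
#' and the whole effect vector is rescaled so the realized sample variance
#' of the genetic component equals `true_h2` exactly. Noise is N(0,
#' 1 - true_h2) and the returned phenotypes are standardized.
#'
#' @param g a standardized [genotype_matrix()] (typically after pruning).
#' @param cfg a [sim_config()]; architecture fields and `true_h2` are used.
#' @param n_reps number of independent phenotype replicates (same causal
#'   variants and effects, fresh noise).
#' @param seed seed for this call (default `cfg$seed + 1` so genotype and
#'   phenotype draws are decoupled but both flow from the config seed).
#' @return list with `y` (n x n_reps matrix of standardized phenotypes;
#'   drop to a [phenotype_vector()] via `[,1]` as needed), `causal`
#'   (variant indices), `beta` (rescaled effects) and `genetic` (the shared
#'   genetic component).
#' @export
simulate_phenotype <- function(g, cfg, n_reps = 1, seed = cfg$seed + 1) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "sim_config"))
  if (g$state != "standardized")
    stop("simulate_phenotype requires standardized genotypes")
  set.seed(seed)
  n <- n_samples(g); m <- n_variants(g)

  genes <- unique(g$variants$gene)
  n_causal_genes <- max(1L, round(cfg$frac_causal_genes * length(genes)))
  causal_genes <- sample(genes, n_causal_genes)
  cand <- which(g$variants$gene %in% causal_genes)
  n_causal <- max(1L, round(cfg$frac_causal_variants * length(cand)))
  causal <- sort(sample(cand, n_causal))
  if (length(causal) == 0) stop("no causal variants selected")

  h2 <- cfg$true_h2
  if (h2 > 0) {
    beta <- stats::rnorm(length(causal))
    gb <- as.numeric(g$dosages[, causal, drop = FALSE] %*% beta)
    gb <- gb - mean(gb)
    s <- sqrt(mean(gb^2))
    if (s == 0) stop("degenerate genetic component; draw more causal variants")
    scale_f <- sqrt(h2) / s
    beta <- beta * scale_f
    gb <- gb * scale_f
  } else {
    beta <- rep(0, length(causal))
    gb <- rep(0, n)
  }
  eps <- matrix(stats::rnorm(n * n_reps, 0, sqrt(1 - h2)), n, n_reps)
  Y <- gb + eps
  Y <- sweep(Y, 2, colMeans(Y), "-")
  Y <- sweep(Y, 2, sqrt(colMeans(Y^2)), "/")
  list(y = Y, causal = causal, beta = beta, genetic = gb)
}

#' Calibration experiment over pruning scenarios
#'
#' For each pruning scenario: prune the genotypes, build exome-wide blocks,
#' plant a causal architecture on the *pruned* variant set, simulate
#' `n_reps` phenotype replicates, estimate heritability for each, and
#' report the mean estimate, its spread and the bias against the planted
#' heritability. With long-range-correlated genotypes this reproduces the
#' inflation under small-window pruning and its removal under the stringent
#' large-window regime.
#'
#' @param g a standardized [genotype_matrix()] (unpruned).
#' @param scenarios named list of [prune_params()].
#' @param cfg a [sim_config()] providing the causal architecture and
#'   `true_h2` (its `n`, `m` need not match `g`).
#' @param target_size exome-block size.
#' @param n_reps phenotype replicates per scenario (default 20).
#' @param seed seed for the phenotype draws.
#' @return data.frame with one row per scenario: retained variant count,
#'   block count, mean/SD of the estimates, bias, and the Monte Carlo
#'   standard error of the mean.
#' @export
run_calibration <- function(g, scenarios, cfg, target_size = 5000,
                            n_reps = 20, seed = cfg$seed + 1) {
  stopifnot(length(scenarios) >= 1)
  if (is.null(names(scenarios)))
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  rows <- lapply(names(scenarios), function(nm) {
    pr <- ld_prune(g, scenarios[[nm]])
    gp <- pr$genotypes
    bs <- make_exome_blocks(gp, target_size = min(target_size,
                                                  n_variants(gp)))
    sim <- simulate_phenotype(gp, cfg, n_reps = n_reps, seed = seed)
    res <- estimate_h2(bs, sim$y)
    h2s <- vapply(res, `[[`, numeric(1), "h2")
    data.frame(
      scenario = nm,
      r2_max = scenarios[[nm]]$r2_max,
      window_bp = scenarios[[nm]]$window_bp,
      m_retained = n_variants(gp),
      K = length(bs$blocks),
      true_h2 = cfg$true_h2,
      mean_h2 = mean(h2s),
      sd_h2 = stats::sd(h2s),
      bias = mean(h2s) - cfg$true_h2,
      mc_se = stats::sd(h2s) / sqrt(length(h2s)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
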