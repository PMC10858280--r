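#' Construct a phenotype vector
#'
#' One trait per sample, aligned to the genotype sample order. Missing
#' values are allowed until [prepare_phenotype()] imputes them.
#'
#' @param y numeric trait values.
#' @param samples character sample ids (same order as the genotype matrix).
#' @param state one of `"raw"`, `"adjusted"`, `"standardized"`.
#' @return a `phenotype_vector` object.
#' @export
phenotype_vector <- function(y, samples = names(y), state = "raw") {
  state <- match.arg(state, c("raw", "adjusted", "standardized"))
  if (is.null(samples)) samples <- paste0("S", seq_along(y))
  stopifnot(length(samples) == length(y))
  structure(list(y = as.numeric(y), samples = as.character(samples),
                 state = state, excluded = rep(FALSE, length(y))),
            class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("phenotype_vector: %d samples [state: %s], %d missing, %d excluded\n",
              length(x$y), x$state, sum(is.na(x$y)), sum(x$excluded)))
  invisible(x)
}

#' Default medication adjustment rules
#'
#' Standard corrections for treatment effects on biomarkers: statin users
#' have LDL cholesterol and apolipoprotein B divided by 0.7, total
#' cholesterol by 0.8, apolipoprotein A-I by 1.06 and HDL cholesterol by
#' 1.05; users of blood-pressure medication have 10 mmHg added to diastolic
#' and 15 mmHg to systolic blood pressure; users of glucose-lowering drugs
#' are excluded from analysis of glycaemic traits.
#'
#' @return data.frame with columns `medication`, `trait`, `action`
#'   (`divide`, `add` or `exclude_sample`) and `value`.
#' @export
default_medication_rules <- function() {
  rules <- rbind(
    data.frame(medication = "statin",
               trait = c("ldl", "apob", "cholesterol", "apoa1", "hdl"),
               action = "divide", value = c(0.7, 0.7, 0.8, 1.06, 1.05)),
    data.frame(medication = "bp_med", trait = c("dbp", "sbp"),
               action = "add", value = c(10, 15)),
    data.frame(medication = "glucose_med",
               trait = c("glucose", "hba1c"),
               action = "exclude_sample", value = NA_real_)
  )
  rownames(rules) <- NULL
  rules
}

#' Adjust a trait for medication use
#'
#' Applies the rule matching `trait` for each medication column flagged TRUE
#' in `flags`. `divide` rules divide the flagged samples' values by the rule
#' constant (undoing the average treatment effect), `add` rules add it, and
#' `exclude_sample` marks the sample for removal (the caller is responsible
#' for dropping excluded samples from the genotype matrix and re-running the
#' minor-allele-count filter on the reduced sample).
#'
#' @param pheno a [phenotype_vector()] in state `"raw"`.
#' @param trait trait name used to look up rules (e.g. `"ldl"`, `"sbp"`).
#' @param flags data.frame or named list of per-sample logical medication
#'   indicators; column names must match `rules$medication`.
#' @param rules rule table, see [default_medication_rules()].
#' @return the adjusted `phenotype_vector` (state `"adjusted"`) with the
#'   `excluded` field set for samples under an `exclude_sample` rule.
#' @export
adjust_for_medication <- function(pheno, trait, flags,
                                  rules = default_medication_rules()) {
  stopifnot(inherits(pheno, "phenotype_vector"))
  flags <- as.data.frame(flags)
  if (nrow(flags) != length(pheno$y))
    stop("flags must have one row per sample")
  if (!all(rules$action %in% c("divide", "add", "exclude_sample")))
    stop("unknown rule action: ",
         paste(setdiff(rules$action, c("divide", "add", "exclude_sample")),
               collapse = ", "))
  if (any(rules$action == "divide" & (is.na(rules$value) | rules$value <= 0)))
    stop("divide rules require a positive divisor")
  applicable <- rules[rules$trait == trait, , drop = FALSE]
  for (i in seq_len(nrow(applicable))) {
    med <- applicable$medication[i]
    if (!med %in% names(flags)) next
    on_med <- !is.na(flags[[med]]) & flags[[med]]
    if (!any(on_med)) next
    pheno$y[on_med] <- switch(applicable$action[i],
      divide = pheno$y[on_med] / applicable$value[i],
      add = pheno$y[on_med] + applicable$value[i],
      exclude_sample = pheno$y[on_med]
    )
    if (applicable$action[i] == "exclude_sample")
      pheno$excluded <- pheno$excluded | on_med
  }
  pheno$state <- "adjusted"
  pheno
}

#' Rank-based inverse normal transform
#'
#' Blom offset: ranks r (ties averaged) map to qnorm((r - 3/8) / (n + 1/4)),
#' so any monotone transform of the input yields the same output.
#'
#' @param y numeric vector without missing values.
#' @return transformed vector resembling a standard normal sample.
#' @export
inverse_normal <- function(y) {
  r <- rank(y, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(y) + 1 / 4))
}

#' Prepare a phenotype for heritability estimation
#'
#' Pipeline, in order: winsorize at the given data-scale limits; mean-impute
#' missing trait values; rank-based inverse normal transform
#' ([inverse_normal()]); residualize on the covariates by OLS (with
#' intercept); standardize the residual to mean 0 and variance 1
#' (denominator n). The output is orthogonal to every covariate column, so
#' block regressions downstream need no covariate terms and keep the
#' n - p_k - 1 degree-of-freedom convention.
#'
#' @param pheno a [phenotype_vector()] (state `"raw"` or `"adjusted"`).
#' @param covariates optional data.frame / matrix of per-sample covariates
#'   (age, sex, genetic principal components, ...); missing covariate values
#'   are mean-imputed.
#' @param winsor_limits optional `c(lo, hi)` clipping bounds applied to the
#'   trait before transformation (e.g. assay reportability limits).
#' @return the `phenotype_vector` in state `"standardized"`.
#' @export
prepare_phenotype <- function(pheno, covariates = NULL, winsor_limits = NULL) {
  stopifnot(inherits(pheno, "phenotype_vector"))
  y <- pheno$y
  if (!is.null(winsor_limits)) {
    stopifnot(length(winsor_limits) == 2, winsor_limits[1] <= winsor_limits[2])
    y <- pmin(pmax(y, winsor_limits[1]), winsor_limits[2])
  }
  if (all(is.na(y))) stop("phenotype is entirely missing")
  if (anyNA(y)) y[is.na(y)] <- mean(y, na.rm = TRUE)
  if (stats::sd(y) == 0) stop("phenotype is constant; cannot standardize")
  y <- inverse_normal(y)

  if (!is.null(covariates)) {
    X <- as.matrix(as.data.frame(covariates))
    storage.mode(X) <- "double"
    if (nrow(X) != length(y)) stop("covariates must have one row per sample")
    if (anyNA(X)) {
      mu <- colMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- mu[idx[, 2]]
    }
    X1 <- cbind(`(intercept)` = 1, X)
    qx <- qr(X1)
    if (qx$rank < ncol(X1)) {
      dropped <- colnames(X1)[qx$pivot[(qx$rank + 1):ncol(X1)]]
      stop("collinear covariate column(s): ", paste(dropped, collapse = ", "))
    }
    y <- stats::residuals(stats::lm.fit(X1, y))
  }
  y <- y - mean(y)
  s <- sqrt(mean(y^2))
  if (s == 0) stop("residual phenotype is constant; cannot standardize")
  pheno$y <- y / s
  pheno$state <- "standardized"
  pheno
}

#' Read a phenotype / covariate table
#'
#' Tab-separated, header row, `NA` for missing; must contain a `sample_id`
#' column. Convenience wrapper used by the command-line interface.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("cannot read phenotype file: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = c("NA", ""),
                    check.names = FALSE, stringsAsFactors = FALSE)
}
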