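Package: rarity
Title: Rare-Variant Heritability by Block-Wise Adjusted R-Squared
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assumption-light estimation of the narrow-sense heritability
    contributed by rare coding variants. Genotype blocks are fitted by
    ordinary least squares and per-block adjusted R-squared values are summed
    into an exome-wide heritability estimate with Wald confidence intervals.
    Includes genotype quality control (missingness, Hardy-Weinberg exact
    test, minor-allele count and frequency filters), windowed LD pruning
    with the stringent long-range regime required for rare variants,
    gene-burden / gene-wise / exome-wide block constructs, phenotype
    preparation (medication adjustment, winsorization, rank-based inverse
    normal transform, covariate residualization), gene-level F-tests with
    Bonferroni correction, a synthetic genotype and phenotype simulator for
    calibration experiments, a non-central-F power estimator, and
    pathogenicity-score enrichment curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
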