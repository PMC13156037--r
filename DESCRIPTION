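Package: koconverge
Title: Convergence Analysis for Pooled CRISPR Knockout Perturbation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analytic and network-based convergence analysis for pooled
    CRISPR knockout (KO) perturbation screens. Implements signed Stouffer
    (sample-size weighted) and inverse-variance meta-analysis with Cochran's Q
    heterogeneity filtering to call convergent genes across KO perturbations;
    rank-rank hypergeometric overlap maps and cross-perturbation correlation
    profiles; consensus co-expression network construction over resampled runs
    with a composite network-convergence score (clustering coefficient, path
    length, semantic coherence, edge reproducibility); ontology-based semantic
    similarity features and a random-forest model predicting convergence
    strength; a Gaussian energy model over bulk plus cell-type expression with
    GRN-sparse precision structure supporting clamped in silico knockouts and
    sign-test convergent-gene calling; hypergeometric over-representation and
    preranked GSEA with leading-edge extraction; CMap-style signature-reversal
    drug queries; behavioral fingerprinting of mutant larvae with a
    five-category drug-rescue classifier; and gRNA abundance normalization for
    sorted-fraction screens. A synthetic-data module generates every input
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    randomForest,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    fgsea,
    metafor
Config/testthat/edition: 3
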