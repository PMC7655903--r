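Package: popgs
Title: Genomic Versus Pedigree Evaluation for Clonally Replicated Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare genomic and pedigree-based genetic evaluation in
    clonally replicated breeding populations such as poplar. Implements
    pedigree relationship matrices (additive and dominance) by the tabular
    method, marker-based pedigree correction via opposing homozygotes,
    VanRaden genomic relationship matrices with trace normalization and
    per-marker weights, Vitezica-style genomic dominance matrices, EM/eigen
    REML with BLUP prediction (single- and multi-trait), the iterative
    weighted G-BLUP scheme, tensor-product B-spline spatial adjustment of
    field trials with AIC knot selection, cross-validation designs that
    sample individuals or whole families, and a battery of prediction-quality
    metrics (predictive ability, accuracy, tier-wise rank correlations, bias
    regression, within-family gain). A synthetic-data module simulates
    factorial and pair mating designs, gene dropping with recombination,
    finite-QTL correlated traits, clonally replicated field trials with
    spatial heterogeneity, and configurable pedigree errors, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    vcfR,
    withr
Config/testthat/edition: 3
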