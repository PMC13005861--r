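Package: polystage
Title: Two-Stage and Single-Stage Genomic Evaluation of Multi-Environment
    Augmented Trials in Autopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic evaluation of unreplicated (augmented
    row-column) multi-environment trials in hexaploid clonal crops such as
    sweetpotato. Provides a dense REML engine for linear mixed models with
    factor-analytic genotype-by-environment structures, heterogeneous
    compound-symmetry non-additive effects, known weight (first-stage error)
    covariances and separable AR1xAR1 spatial residuals; pedigree (A) and
    genomic (G) relationship matrices with hexaploid dosage adjustments;
    stage-one single-environment analyses with BLUE, deregressed-BLUP and
    pedigree-deregressed-BLUP entries and full or diagonal weight matrices;
    the benchmark single-stage model; CV1/CV2 cross-validation, selection
    concordance and genotype-by-environment variance partitioning; and a
    synthetic-data generator that reproduces the statistical structure of
    partial-diallel hexaploid populations tested in augmented row-column
    designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
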