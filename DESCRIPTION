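Package: mkadapt
Title: Adaptive Substitution Rate Estimation from Polymorphism and Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the adaptive amino-acid substitution rate
    (omega_a) from coding-sequence polymorphism and divergence data using
    McDonald-Kreitman style contrasts with an explicit distribution of
    fitness effects (DFE). Builds folded synonymous and non-synonymous site
    frequency spectra (all-mutation and GC-conservative subsets) from
    genotype tables and coding sequences; fits GammaZero, GammaExpo and
    ScaledBeta DFE models by Poisson maximum likelihood with per-class
    nuisance parameters; derives alpha, omega_a and omega_na per species and
    per taxonomic group (pooled-SFS and averaged estimators) with AIC model
    averaging and SNP-bootstrap confidence intervals; provides the
    comparative statistical layer (regressions, Spearman tests, common-slope
    ANCOVA, slope meta-analysis) and a Wright-Fisher forward simulator of
    coding sequences under fluctuating population size to control for
    demographic artifacts. Synthetic-data generators make every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    readxl,
    jsonlite
Config/testthat/edition: 3
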