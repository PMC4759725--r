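Package: mixpsim
Title: Simulation-Based Evaluation of Genomic Prediction with
    Whole-Genome Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of diverged
    livestock populations carrying whole-genome sequence variation,
    quantitative trait simulation from sampled QTL, and genomic
    prediction with SNP-BLUP (ridge regression) and MixP (a
    two-component normal-mixture prior solved by iterative conditional
    expectation). Supports within-population, across-population and
    multi-breed reference designs at whole-sequence and subsampled SNP
    panel densities, with replicated evaluation and linkage
    disequilibrium diagnostics (r-squared decay and persistency of
    phase between populations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
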