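Package: protscreen
Title: Proteome-Wide Mendelian Randomization and Colocalization Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bidirectional two-sample Mendelian randomization and Bayesian
    colocalization screening of circulating plasma proteins against a binary
    disease outcome, built around cis-pQTL instruments. Provides readers and
    validators for GWAS summary statistics, cis instrument selection with
    region merging, LD clumping, allele harmonization with proxy lookup and
    palindromic-strand inference, Wald-ratio and inverse-variance-weighted
    multiplicative-random-effects estimation, Steiger directionality tests
    with liability-scale variance conversion, fixed-effect GWAS meta-analysis
    with genomic control and heterogeneity filtering, approximate-Bayes-factor
    colocalization over nested windows, a multi-criterion causal-candidate
    decision engine, and a summary-statistics simulator with known causal
    architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
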