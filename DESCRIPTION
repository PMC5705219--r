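Package: meiomap
Title: Likelihood-Based ChIP-Seq Peak Calling, Mixture Motif Discovery, and
    Repeat-Family Association for Meiotic Recombination Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and interrogating zinc-finger protein binding
    maps of the kind used to study PRDM9 and meiotic recombination hotspots.
    Implements per-base Poisson likelihood-ratio peak calling against a local
    background estimated from an input (total chromatin) control, enrichment
    estimation with profile-likelihood confidence intervals and force-calling
    of fixed windows; Bayesian mixture de novo motif discovery with 10-mer
    seeding, EM refinement, motif extension and strand-aware posterior match
    assignment; chance-corrected interval-overlap statistics (analytic and
    shift-based); repeat-family k-mer association with conditional logistic
    forward selection under Bonferroni control; aggregate signal profiles
    with kernel smoothing; and a synthetic-data generator with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
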