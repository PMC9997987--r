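Package: methcap
Title: Conversion-Aware Bait Design and Evaluation for Targeted Methylation
    Sequencing
Version: 0.1.0
Authors@R:
    person("methcap", "maintainers", email = "methcap@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing hybridization-capture baits against
    enzymatically or bisulfite converted DNA and for evaluating the resulting
    targeted methylation libraries. Baits are tiled over target regions,
    expanded into the nine methylation-state/strand permutations a converted
    library can present, screened for cross-hybridization against converted
    genome variants with a deterministic seed-and-extend local aligner, and
    filtered on repeat masking, GC content and hit counts. Evaluation covers
    Bismark-style CpG callsets: depth filtering, target intersection,
    matched-site Pearson correlations, per-region mean methylation, paired
    t-tests, spike-in conversion controls, and seeded synthetic data
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
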