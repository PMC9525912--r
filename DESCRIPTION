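Package: triomics
Title: Single-Sample Metabolite, Histone-Modification and Protein
    Quantification from Mass Spectrometry Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative core of a single-sample multi-omic ("triomics")
    LC-MS workflow. Provides elemental-formula mass arithmetic with
    dansyl and O-benzylhydroxylamine derivatization chemistry, ppm-based
    matching of LC-MS features to a derivatized compound library,
    internal-standard concentration estimation with retention-time-zone
    assignment rules, SILAC-normalized (ratio-of-ratios) histone
    post-translational-modification quantification from parallel reaction
    monitoring peak areas, isotopologue natural-abundance correction and
    stable-isotope enrichment estimation, TMT six-plex reporter
    aggregation with PSM-level filters, and a SAM-style permutation
    differential statistic with the s0 exchangeability constant.
    Ground-truth simulators for every input format make the full pipeline
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
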