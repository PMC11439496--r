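Package: b12screen
Title: Phylogenomic Screening of Vitamin B12-Associated Metabolism in Plants and Algae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for detecting homologues of vitamin
    B12-associated protein families (methionine synthase isoforms METH and
    METE, MTRR, adenosylcobalamin-dependent enzymes, cobalamin trafficking
    proteins and the uptake protein CBA1) across mixed genome and
    transcriptome protein libraries. Candidates are retrieved by local
    alignment with reciprocal best-hit validation, curated on
    neighbour-joining trees by iterative long-branch removal, screened for
    bacterial contamination versus horizontal gene transfer, validated by
    protein domain architecture, and aggregated into per-species
    presence/absence matrices and B12 metabolic status calls. A synthetic
    cohort generator with known evolutionary ground truth (gene loss,
    horizontal transfer, contamination, transcript truncation) supports
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
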