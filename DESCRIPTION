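Package: bcpflow
Title: B-Cell Precursor Maturation Profiling from Cytometry and IGH Repertoire Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of human bone-marrow B-cell precursor (BCP)
    maturation. Generates multi-donor 10-marker cytometry event tables and
    compartment-specific IGH V(D)J rearrangement repertoires with known ground
    truth; gates BCP stages (pro-B, pre-BI, pre-BII, immature, mature) from
    BCR-associated markers; builds a pooled-healthy-control principal-component
    reference with per-population 2SD Mahalanobis contours to quantify
    transitioning/aberrant cells and call maturation blockades typical of
    RAG or BTK deficiency; and computes clone-level repertoire statistics
    (in-frame fraction, CDR3 length and charge distributions) for sorted
    pre-B subpopulations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
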