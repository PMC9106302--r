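Package: insulatr
Title: Insulation Scoring and Contact-Domain Boundary Analysis for Hi-C Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify chromosomal contact-domain boundaries from Hi-C
    data and to measure their dependence on architectural proteins. Implements
    read-pair filtering and binning, iterative-correction (ICE) matrix
    balancing, a physical insulation score with multi-scale boundary calling,
    cross-genotype boundary harmonization and lost/weaker/intact
    classification, A/B compartment eigenvector analysis, ChIP peak and
    annotation integration, Capture-C viewpoint profiling, and quantification
    of enhancer-blocking insulator strength from reporter flow cytometry.
    Includes a synthetic-data generator that plants domains, compartments,
    peaks, and reporter strengths with known ground truth so that every stage
    of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
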