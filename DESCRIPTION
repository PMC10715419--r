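Package: uremicomics
Title: Integrated Serum Metabolomics and Proteomics of Hemodialysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for integrated untargeted serum
    metabolomics and TMT proteomics of end-stage kidney disease patients
    undergoing hemodialysis. Implements feature-level quality-control
    filtering of LC-MS feature tables, median normalization and
    per-feature differential abundance testing across healthy control,
    pre-dialysis and post-dialysis groups, tri-category classification of
    uremic solutes by dialysis clearance, confirmation of candidate
    metabolites against reference standards by accurate mass, retention
    time and MS2 spectral similarity, quantile normalization and
    differential calling of TMT reporter intensities, hypergeometric
    pathway over-representation, assembly of a metabolite-protein disease
    interactome with one-hop neighbors, and four-parameter logistic
    dose-response fitting with IC50 reporting. A synthetic-data module
    generates every input with known ground truth so the full pipeline is
    testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    igraph,
    minpack.lm,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
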