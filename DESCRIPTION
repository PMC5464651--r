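Package: redirectomics
Title: Mutual-Information Screening of Gene-Set Signatures for Cancer
    Cell Redirection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens curated gene-set signatures for evidence of cancer cell
    redirection from bulk expression data. Signatures are scored by the ratio
    of mutual information between normal and redirected sample groups to the
    mutual information between redirected and tumor groups, computed over
    discretized log2 intensities; significance is called against a fitted null
    ratio distribution with Bonferroni control. Includes classical
    multidimensional scaling of samples on inverse-mutual-information
    dissimilarities, moderated-t differential expression with the core
    biomarker selection rule (unchanged normal-vs-redirected, changed in both
    tumor contrasts), interaction-based signature extension, a seeded
    synthetic-data generator emulating the six-group replicate design, and a
    pipeline orchestrator with reproducible manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
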