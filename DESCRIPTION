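Package: maldiconcord
Title: Cross-Modality MALDI Lipidomics Concordance and Smoke-Exposure
    Response Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative MALDI-TOF lipidomics of cerebral white
    matter: peak picking and total-ion-count normalization of profile
    spectra, replicate aggregation into consensus peak lists,
    cross-modality (lipid extract versus imaging mass spectrometry) ion
    matching, C13 isotope satellite flagging, five-level
    relative-abundance concordance classification, row z-scored Euclidean
    hierarchical clustering and principal component analysis, and
    classification of cigarette-smoke exposure and withdrawal response
    patterns across an A8/CS4/CS8/CS8+R design.  Includes a
    synthetic-data generator emulating the four-group, six-replicate,
    two-modality study layout for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, grDevices, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, pheatmap
Config/testthat/edition: 3
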