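Package: phrenoscope
Title: Quantification of Left/Right Asymmetry in Diaphragm Innervation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric morphometry of phrenic nerve branching patterns on
    whole-mount diaphragm preparations (defasciculation distance,
    secondary-branch counts, split angles, endplate-band thickness),
    concentric-ring quantification of axon outgrowth from spinal-cord
    explants, a paired left/right transcript-lateralization filter for
    multi-embryo expression data, assay-level quantifiers (RNAscope surface
    ratios with cross-applied thresholds, in situ zymography fractions,
    western-blot pair normalization), exact small-sample Mann-Whitney and
    Wilcoxon signed-rank tests, and synthetic-data generators with known
    ground truth for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
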