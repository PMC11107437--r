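Package: furascope
Title: Correlating Per-Cell RNAscope Signal with Fura-2 Calcium Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for joint single-cell functional and
    transcript-level phenotyping of cultured sensory neurons. Quantifies
    ratiometric Fura-2 (F340/F385) calcium responses as baseline-corrected
    areas under the curve with a KCl viability gate, quantifies per-cell
    RNAscope in situ hybridization signal from confocal Z-stacks, aligns
    the confocal frame to the wide-field functional frame with a similarity
    transform propagated to all channels and ROIs, derives mean + 2*SD
    response thresholds (iterative trimmed Gaussian fit for the functional
    modality, intra-day negative controls for RNAscope), classifies cells
    into the four concordance categories, and computes the Pearson
    correlation between mRNA signal and agonist response on the union set.
    Includes a seeded synthetic-data generator emulating the imaging study
    so the full pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    rlang,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma,
    ggplot2,
    optparse
Config/testthat/edition: 3
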