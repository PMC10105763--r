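Package: lsfgbom
Title: Resistivity Mapping for Laser Speckle Flowgraphy Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the beat strength over mean blur rate (BOM), a
    heart-rate-independent ocular blood-flow resistivity index, from laser
    speckle flowgraphy (LSFG) image sequences.  Implements sparse spectral
    estimation of the pulsatile waveform on a sine/cosine dictionary,
    rubber-band region-of-interest analysis with automatic vessel/tissue
    delineation, flow-driven SLIC superpixel segmentation for two-dimensional
    BOM maps, and Monte-Carlo machinery that quantifies the speckle-noise bias
    between superpixel and rubber-band averaging.  A synthetic pulsatile flow
    phantom with known ground-truth resistivity makes the full pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    tiff,
    yaml,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
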