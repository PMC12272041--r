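Package: dropnet
Title: Quantification of Patterned Gene Expression Induced by Picoliter
    Droplet Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify patterned reporter-gene expression induced in
    bacterial lawns by 3D-printed picoliter droplet networks. Implements the
    pattern-fidelity (PF) index from two-channel epi-fluorescence micrographs
    (expression channel plus a cascade-blue-dextran footprint channel),
    including activation and footprint masking, intended/unintended/no-expression
    area decomposition, activated-pixel intensity statistics, and the
    volume-to-surface-area ratio of a droplet network. Also provides
    hex-packed rasterization of printing maps, a synthetic micrograph
    generator with exact geometric ground truth, heat-induced shrinkage
    analysis, micro-colony density counting, and normality-gated two-group
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
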