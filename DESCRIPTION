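Package: FibreForge
Title: Hierarchical Coiled-Coil Fibre Assembly Modelling with SAXS and EM Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the hierarchical self-assembly of the SYCE2-TEX12 coiled-coil
    complex into discrete-length 2-nm, 4-nm, 10-nm and bundled fibres, and provides
    the two measurement pipelines used to test such models: rod-geometry analysis of
    small-angle X-ray scattering curves (Guinier Rg, cross-sectional Rc, regularized
    P(r) inversion with Shannon-limit flagging, chi-square model fitting, SEC-series
    analysis) and ridge-detection quantification of curvilinear fibres in negative
    stain electron micrographs (bandpass preprocessing, Steger-style line detection
    with sub-pixel width estimation, width-population statistics). Includes coarse
    bead-model builders with Debye forward scattering, crystallographic d-spacing
    helpers, heptad-register analysis of assembly-interface residues, and
    seed-deterministic synthetic-data generators for SAXS curves, micrographs and
    SEC elution series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    pracma,
    mclust,
    jsonlite,
    yaml,
    tiff,
    png,
    bio3d,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
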