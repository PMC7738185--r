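Package: valveQuant
Title: Multiscale Quantification of Heart-Valve Leaflet Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for multiscale characterization of
    tricuspid valve anterior leaflet tissue: planar biaxial mechanics
    (deformation gradients from fiducial markers, membrane tension,
    J-curve stiffness metrics), leaflet morphometry and spline-normal
    thickness profiling, regional immunohistochemistry positive-pixel
    quantification with fold-change maps, through-depth collagen fiber
    orientation analysis with axial von Mises fits, nuclei morphometry,
    colorimetric collagen-assay quantification, a label-free proteomics
    differential-expression filter, and a normality-gated statistical
    test dispatcher. Includes seeded synthetic-data generators with
    known ground truth for every modality, so the full pipeline is
    testable end to end without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    mgcv,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
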