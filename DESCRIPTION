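Package: conitherm
Title: Infrared Thermography Analysis of Drought Stress in Conifer Seedlings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for assessing drought stress in potted conifer
    seedlings from radiometric thermal images. Provides synthetic
    thermal-scene and experiment-table generators with known ground truth,
    histogram-based segmentation of plant tissue from heated backgrounds
    (unsharp masking, intermodes thresholding, Sobel edge removal),
    emissivity handling, the crop water stress index (CWSI) and stomatal
    conductance index (Ig) computed against artificial wet and dry
    reference surfaces, vapor pressure deficit and percent soil water
    deficit covariates, and random-intercept mixed-effects modelling of
    the indices against soil water deficit or irrigation treatment with
    AIC-guided simplification, scenario contrasts, curvature tests,
    response-magnitude statistics and false-discovery-rate corrected
    multiple comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    nlme,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
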