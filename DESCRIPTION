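Package: retinotex
Title: Texture and Optical-Property Analysis of Segmented Retinal OCT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intraretinal layers of macular optical coherence
    tomography (OCT) radial scan sets beyond thickness: gray-level
    co-occurrence contrast, power-spectrum fractal dimension of axial
    reflectance profiles, layer index and total reflectance after
    normalization to the retinal pigment epithelium reference layer.
    Includes complex diffusion speckle denoising, vessel-shadow exclusion,
    scan-quality gating, a layered B-scan phantom and cohort simulator
    with ground truth, and mixed-model group comparisons that account for
    inter-eye correlation within subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    lme4,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
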