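Package: visadapt
Title: Visual Pigment Templates, Lens Refractivity and Expression Tools
    for Metamorphic Visual Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying visual adaptation across amphibian
    metamorphosis. Implements closed-form A1 (retinal) and A2
    (3,4-didehydroretinal) visual pigment absorbance templates
    parameterized by lambda-max; a microspectrophotometry (MSP)
    spectrum-processing pipeline (scan merging, Gaussian peak
    estimation on the top data points, normalization, template fitting
    by long-wavelength limb grid search, chromophore classification and
    photoreceptor class summaries); protein refractive index increment
    (dn/dc) estimation from amino-acid composition under stated optical
    conditions, with expression-weighted lens summaries; trimmed mean
    of M-values (TMM) cross-sample normalization; an unconditional
    exact Z-pooled test for 2x2 direction-count tables; and seeded
    synthetic-data generators so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
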