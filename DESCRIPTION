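Package: notch3score
Title: Quantitative Scoring of Vascular NOTCH3 Accumulation in Immunostained Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implementation of the NOTCH3 score, a quantitative
    immunohistochemistry biomarker for vascular NOTCH3 protein accumulation
    in CADASIL models. Provides the mouse brain-section scoring pipeline
    (8-bit conversion, unsharp-mask enhancement, intensity thresholding,
    connected-particle analysis with size and circularity filters), the
    human CD31-masked vessel variant, the accompanying statistical layer
    (summary t-tests, one-way ANOVA with Fisher's LSD, progression-slope
    estimation and comparison, power analysis), a synthetic DAB-stained
    field and cohort generator with ground truth, and a cohort scoring
    pipeline producing analysis-ready tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'biostats.R'
    'enhance.R'
    'notch3score-package.R'
    'particles.R'
    'vessel.R'
    'synth.R'
    'pipeline.R'
    'raster-io.R'
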