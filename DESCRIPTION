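Package: HaloScreen
Title: Simulation and Analysis of Encoded-Microbead Aptamer Binding Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for multiplex fluorescence microbead binding assays in
    which dye/size-encoded bead populations carry capture proteins and bound,
    fluorescently labelled aptamers form a halo at the bead rim. Provides a
    synthetic chip-image generator with ground truth; bead detection,
    encoding-feature measurement and population decoding; annulus-based halo
    quantification aggregated to the referenced mean fluorescence intensity
    (rMFI) per population, including kinetic (frame-series) mode; nonlinear
    dose-response fitting over a panel of log-logistic, Weibull and
    exponential-decay models with AIC selection and ED50 extraction;
    screening statistics (percent change versus a reference condition,
    specificity matrices, ANOVA with many-to-one comparisons against a
    control); and protein net charge and isoelectric point computation from
    sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    EBImage,
    minpack.lm,
    Biostrings,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'HaloScreen-package.R'
    'chipio.R'
    'detect.R'
    'decode.R'
    'doseresponse.R'
    'panel.R'
    'protein.R'
    'quantify.R'
    'screenstats.R'
    'simconfig.R'
    'simulate.R'
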