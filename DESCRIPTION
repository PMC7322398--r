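Package: guvfrap
Title: FRAP Diffusion and Membrane Composition Analysis for Giant
    Unilamellar Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lateral lipid diffusion in giant unilamellar
    vesicle (GUV) membranes from fluorescence recovery after
    photobleaching (FRAP) time series, using the uniform-disk
    closed-form recovery model to convert fitted half-life recovery
    times into diffusion coefficients, with the standard
    quality-control rules for spot geometry, bleach-pulse duration and
    mobile fraction.  Also quantifies binary lipid membrane composition
    from equatorial-ring fluorescence via zero-intercept regression and
    slope normalization.  Includes a synthetic-data generator (recovery
    traces, confocal-like image stacks, composition datasets) and a
    Brownian particle simulator that serves as a physics oracle for the
    closed form, so the whole pipeline is testable without microscope
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
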