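Package: saffusion
Title: Mid-Level Data Fusion of TLC Imaging and Raman Spectra for
    Saffron Adulteration Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening saffron powder for economic adulteration by
    fusing two cheap, field-deployable measurements: thin-layer chromatography
    (TLC) pattern images taken under ambient and 365 nm UV light, and Raman
    spectra collected on the TLC substrate. The package extracts featured
    imaging variables (windowed channel statistics at midplane and ring
    sampling points) and featured Raman variables (crocin band windows),
    min-max normalizes and concatenates the blocks into a mid-level fused
    matrix, and fits NIPALS partial least squares models for adulterant
    classification (PLS-DA with Pareto scaling) and spike-level
    quantification, with grouped cross-validation, VIP variable selection,
    misclassification tables and R2/RMSECV/RMSEP summaries. A synthetic-data
    generator emulates the full measurement design (four adulterants at five
    spike levels plus pure saffron, replicated spectra and patterns, linear
    spectral mixing, channel saturation) so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
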