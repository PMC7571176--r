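Package: ramanpen
Title: In-Situ Confocal Raman Depth Profiling of Skin Penetration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing pipeline for confocal Raman microscopy depth scans of
    drug penetration into stratum corneum: cosmic-ray spike removal,
    shape-based fluorescence background subtraction, PCA noise reduction,
    band-area depth profiles by trapezoidal integration, skin-surface
    localization from the keratin 1008 1/cm band, profile cropping and
    normalization, cumulative depth AUCs and formulation enhancement ratios.
    Includes axial-resolution (FWHM) and film-thickness validation metrics
    and a synthetic hyperspectral scan generator with known ground truth for
    caffeine-incubated skin, a silica plate and a PET film.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
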