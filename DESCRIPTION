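Package: thermobat
Title: Supraclavicular Brown Adipose Tissue Activity from Infrared
    Thermography, Cross-Validated Against PET-Derived Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying supraclavicular brown adipose tissue (BAT)
    activity from radiometric infrared thermography and for comparing the
    thermal hotspot spatially and quantitatively with glucose-uptake maximum
    intensity projections (MIP) from dynamic FDG PET/CT. Provides Planck-law
    conversion between raw camera counts and temperature with an open 16-bit
    PNG + JSON frame format, semi-automated supraclavicular region-of-interest
    construction from five anatomical apices with a gradient-tracked neck
    contour, hotspot (hottest-10 percent median) time-series extraction with
    moving-average smoothing and base/peak/delta outcomes, similarity-transform
    frame registration and difference-video rendering, coronal maximum
    intensity projection of scalar volumes, locally weighted mean (LWM)
    control-point warping between thermal and MIP coordinates, hotspot spatial
    overlap and cohort statistics, and a synthetic phantom generator with
    closed-form ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    pracma,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tools,
    withr
Config/testthat/edition: 3
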