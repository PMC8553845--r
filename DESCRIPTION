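Package: facetmap
Title: Pseudopupil-Based Mapping of Compound-Eye Sampling Resolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to estimate local interommatidial angles (delta-phi) of
    insect compound eyes from pseudopupil observations acquired over a
    two-axis goniometer scan.  Provides hexagonal facet-lattice geometry,
    a synthetic eye generator driven by a parametric acuity field (with a
    honeybee-forager preset and rendered fluorescent/dark pseudopupil
    image frames), sub-pixel pseudopupil centre detection with intensity
    profiles and landmark-based lattice registration, finite-difference
    recovery of the local angular magnification into acuity maps of the
    visual field, and an end-to-end parameter-recovery harness.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
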