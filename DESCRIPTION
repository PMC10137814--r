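Package: pixelLV
Title: Pixel-Based Left-Ventricular Volumetry from Short-Axis Cine MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automatic pixel-based measurement of left-ventricular
    function parameters (EDV, ESV, SV, EF) from short-axis cine MRI.
    Implements brush-seeded region growing bounded by local intensity
    statistics with morphological closing, the 50%-ring basal-slice rule,
    Simpson-rule volume summation, a contour-surface (disc-area) reference
    emulation, four closed-form papillary-muscle volume estimators, paired
    TOST equivalence testing with a Cohen's d margin, and a ground-truthed
    synthetic cine phantom generator so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
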