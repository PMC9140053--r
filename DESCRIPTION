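Package: renalsrus
Title: Super-Resolution Ultrasound Velocimetry of the Renal Microvasculature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ultrasound localization microscopy (ULM) analysis of renal
    microvascular haemodynamics: sub-pixel microbubble localization by
    weighted centroids, patch-based non-rigid motion compensation from
    interleaved B-mode frames, hierarchical Kalman multi-target tracking,
    super-resolved density and RGB direction/velocity maps, direction-based
    separation of arterial and venous tracks in the renal cortex, outer
    medulla and inner medulla, and injection-aligned velocity statistics
    (moving averages, repeated-measures ANOVA with Greenhouse-Geisser
    correction, Tukey post-hoc tests). Includes a synthetic renal-flow
    phantom and frame simulator with a prazosin hemodynamic model so the
    whole pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
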