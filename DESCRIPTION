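Package: electrotax
Title: Quantification of Planarian Electrotaxis from Arena Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates, tracks and scores planarian electrotaxis assays run
    in narrow trough arenas under a static electric field with a
    mid-experiment polarity swap. Provides a biased persistent random-walk
    simulator with backlit image-stack rendering, centroid tracking via
    background subtraction and largest-blob extraction, the cathode-quadrant
    occupancy and toward-cathode movement fractions (f_cat-1/2, f_mov-1/2),
    head/body morphometric ratios, and the associated statistical battery
    (one-way and factorial ANOVA, Dunnett and Tukey post hoc tests,
    repeated-measures models, Bonferroni-adjusted paired t-tests,
    assumption checks, and randomization tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    EBImage,
    car,
    lmtest,
    multcomp,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
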