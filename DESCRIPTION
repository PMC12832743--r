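Package: sonopupil
Title: Automated Ultrasound Pupillometry: Simulation, Segmentation, and
    Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the pupillary light reflex (PLR) from
    transpalpebral B-mode ultrasound cine loops. Provides a synthetic
    speckle-noise cine generator with analytically known ground truth, a
    four-stage pupil segmentation pipeline (intensity thresholding,
    morphological filtering, component tracking, maximal horizontal chord
    through the pupil centroid), derivation of the six standard PLR metrics
    (initial and end-constriction diameter, constriction ratio, latency,
    average constriction and dilation velocity) with triplicate averaging
    and quality control, and the full method-comparison and reliability
    battery used in paired pupillometry studies: Bland-Altman bias and 95%
    limits of agreement, ordinary least-squares regression, Pearson
    correlation with Fisher-z confidence intervals, proportional-bias
    regression, intraclass correlation coefficients ICC(2,1) and ICC(3,1),
    and Shapiro-Wilk normality screening. An end-to-end study emulator
    reproduces a paired two-modality, two-observer eye-level design with
    fixed seeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
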