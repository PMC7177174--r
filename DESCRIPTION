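Package: interseg
Title: Simulated User Interaction for Semi-Automated 3D Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulated-rater framework for measuring how the accuracy of
    semi-automated 3D lesion segmentation changes with the level of user
    interaction. Mimics a radiologist's real-time workflow on multi-planar
    reformatted (MPR) MR volumes: drawing long and short axes on a chosen
    axial slice, dropping boundary points where the evolving contour
    disagrees with ground truth, refining on coronal and sagittal planes,
    and editing to perfection. Includes four long-axis drawing strategies
    (true longest, medial, statistical scoring with Parzen-window
    Kullback-Leibler divergence, and endpoint sweeping), a reference
    probabilistic region-growing engine, a seeded synthetic lesion phantom
    generator, Dice-coefficient evaluation with per-patient aggregation,
    and an end-to-end experiment runner producing summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
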