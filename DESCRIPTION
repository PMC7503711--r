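Package: lipograin
Title: Morphometry, Immunolabel Quantification and Segmentation
    Evaluation for Lipoprotein Electron Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for quantitative electron microscopy of plasma
    lipoprotein nanoparticles imaged in positive-contrast mixed-metal
    methylcellulose films. Simulates calibrated micrographs of dark-rimmed
    spheroidal particles with full ground truth; measures particles
    (horizontal calliper diameters, moment-equivalent axes, oblate-spheroid
    orientation correction, binned size distributions, edge-contrast
    profiles); applies unbiased stereological selection rules (central
    evaluation window with a 50 percent area criterion, forbidden and
    acceptance scanning lines, systematic uniform random field sampling);
    quantifies antibody labelling and antibody-induced aggregation
    (label densities per particle, labelled fractions, aggregate censuses
    with chi-square comparisons); ships a classical radial-symmetry
    baseline instance segmenter; and evaluates any instance segmentation
    against ground truth with detection rate, false detections per 100,
    COCO-style mean average precision over IoU 0.50-0.95, Bland-Altman
    size agreement and overlapping-pair counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    png,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
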