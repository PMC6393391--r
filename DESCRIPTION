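Package: skelasso
Title: L1-Sparse Refinement of Neuron Skeletons Against 3-D Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Corrects initial neuron reconstructions (SWC) against the 3-D
    grayscale image stacks they were traced from. Intermediate skeleton
    points are refined with a Lasso-type model solved by split-Bregman
    (ADMM) iterations: an image-intensity attraction term plus an L1
    penalty on discrete second differences, which keeps genuine corners
    while flattening noise-induced wiggles. Branch points are refined by
    recombining the three incident segments pairwise, scoring candidate
    positions on a Gaussian skeleton-template image with an orientation
    prior, and averaging the three estimates. Includes a synthetic
    phantom generator (fold-line neurites and Y junctions with Gaussian
    blur and noise), a whole-tree workflow, and morphometry (total
    length, local branch angles, matched-pair segment distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tiff,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    utils
Config/testthat/edition: 3
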