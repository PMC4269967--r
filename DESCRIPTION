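Package: cytoverlap
Title: Detection of Overlapping Nuclei in Cervical Cytology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised detection of overlapping cell nuclei in Pap smear
    micrographs. Candidate nucleus boundaries are extracted with a
    hue-gated, gradient-based morphological pipeline (Sobel magnitude,
    Canny-style edge filtering, size and closed-contour filtering, spur
    and bifurcation pruning); each candidate region is summarised by a
    five-feature shape and texture descriptor (eccentricity, axis ratio,
    equivalent-to-actual diameter ratio, number of grayscale local
    minima, and maximum inter-minima distance); regions are then
    clustered into overlapped versus single nuclei with k-means or fuzzy
    c-means. Includes a ground-truthed synthetic cervical scene
    generator, Tanimoto/precision/recall/F1 evaluation utilities, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    jsonlite,
    optparse,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
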