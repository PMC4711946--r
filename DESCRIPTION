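Package: vesselquant
Title: Quantification of Vessel-Wall Components in Trichrome-Stained Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage quantification of smooth-muscle-fiber (SMF) and
    extracellular-matrix (ECM) areas in Masson's-trichrome-stained vessel-wall
    sections. A pre-processing stage converts images to CIELab, removes tissue
    folds and blood residues, stretches contrast, binarizes with Otsu's method
    and cleans the wall mask with DBSCAN. A feature-extraction stage clusters
    wall pixels by color with k-means and reports normalized component areas.
    Group differences in the normalized areas are assessed with seeded,
    parallelizable permutation tests including Monte-Carlo p-value confidence
    intervals. A synthetic vessel-image generator with ground-truth masks
    supports validation without access to stained sections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    yaml,
    optparse,
    EBImage
Config/testthat/edition: 3
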