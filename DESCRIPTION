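Package: skeletrace
Title: Dimension-Aware Skeletonization and Tracing of Cryo-Electron Tomogram Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of semantic segmentations of cryo-electron
    tomograms. Converts binary segmentations of membranes, filaments and
    macromolecules into dimension-specific skeletons by non-maximum
    suppression along Hessian eigenvector directions, traces filament
    networks as spatially embedded graphs and extracts discrete curves
    with local and global geometric descriptors (curvature, torsion,
    sinuosity, persistence length), localizes particle centers by mean
    shift, and provides topology-aware segmentation comparison metrics
    (skeleton-based Dice at dimension d, skeleton precision, detection
    F1). Includes geometric phantom generators with exact ground truth
    and MRC2014 volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
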