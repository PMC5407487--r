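Package: kymoclock
Title: Temporal Ordering of Segmentation-Clock Expression Snapshots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies fluorescence intensity along the normalized
    rostro-caudal axis of presomitic mesoderm (PSM) explants, assembles
    per-channel intensity matrices, and infers the temporal order of
    static snapshots of oscillatory gene expression by minimizing a
    circular-autocorrelation periodicity objective with a Metropolis
    annealing search over permutations.  Includes a synthetic
    traveling-wave cohort generator with known ground-truth phases,
    ordered-kymograph assembly with periodic extension, phase
    classification of clock-gene profiles, and deterministic CSV/JSON/PNG
    readers and writers for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    tiff,
    png,
    xml2,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
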