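Package: spotfuse
Title: Joint Non-Negative Matrix Factorization of Spatial Transcriptomics and Histology Features
Version: 0.1.0
Authors@R: person("Spotfuse", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Jointly factorizes a spot-by-gene expression matrix and a paired
    spot-by-image-feature matrix into a shared spot-by-factor matrix and two
    modality-specific loading matrices using accelerated hierarchical
    alternating least squares (A-HALS). Includes rank selection by four-block
    bi-cross-validation, half-normal and NNDSVD initialization, multiscale
    patch histogram feature extraction from H&E images, factor clustering and
    evaluation against reference annotations, a synthetic paired-data
    generator, readers for Matrix Market spot bundles, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    clue,
    igraph,
    jsonlite,
    optparse,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
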