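Package: cqcnn
Title: Hybrid Classical-Quantum Convolutional Networks for Brain-MRI Slice
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for binary classification of 2D brain-MRI slices with a
    lightweight hybrid classical-quantum convolutional neural network. Provides
    an edge-trimmed, evenly spaced 3D-to-2D volumetric slice extractor for
    NIfTI images, an exact statevector simulator for the ZZ-feature-map /
    Ry-ansatz parameterized quantum circuit with parameter-shift gradients, the
    hybrid architecture and a matched-parameter classical control model,
    training and evaluation harnesses with multi-run convergence diagnostics,
    and seeded synthetic phantom generators (3D volumes and two-class image
    sets with tunable inter-class similarity) so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
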