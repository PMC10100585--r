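Package: solvmap
Title: Monte Carlo Image Solvability Maps for Tomographic Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Grades how stably each pixel of a tomographic image can be
    reconstructed under a given parallel-beam acquisition geometry and
    iterative algorithm. Many random ellipse phantoms are simulated on a
    fine grid, projected, corrupted with Poisson noise, binned down and
    reconstructed at coarse resolution with gradient-descent or ML-EM
    solvers (optionally with finite-support and truncation-modification
    constraints); the per-pixel average of squared reconstruction errors
    is the image solvability map. Includes an exact Siddon ray-driven
    projector, the Kirillov angular-coverage region-of-interest
    predictor, and dense SVD diagnostics (condition number and the
    diagonal of the Moore-Penrose projector) for small systems.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
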