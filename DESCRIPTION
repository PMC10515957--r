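Package: densedemix
Title: Denoise, Sparsen, Detect and Demix Dense Calcium Imaging Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for extracting neural signals from densely mixed
    calcium imaging movies (e.g. Bessel-beam volumetric projections), where
    many neurons contribute to each pixel. The movie is noise-normalized and
    rigidly registered, compressed and denoised by patchwise adaptive-rank
    SVD with interpolated stitching into a sparse spatial basis, temporally
    sparsened by AR(1) deconvolution (an online active-set solver, or a fast
    naive operator acting on the temporal basis), and re-denoised by
    projection onto the spatial basis. Isolated neuron footprints are then
    detected in the brightest sparsened frames through a pluggable detector
    interface, and the full movie is demixed by constrained nonnegative
    matrix factorization with hierarchical alternating least squares, a
    simplified ring neuropil model, and a superpixel multi-pass on the
    residual. A ground-truthed movie simulator and a recovery-accuracy
    evaluation harness (greedy matching, false-positive count, oracle
    baseline, demixing-video export) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
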