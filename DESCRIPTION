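Package: schicdd
Title: Diagonal Diffusion Embedding and Clustering of Single-Cell Hi-C Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised embedding and clustering of sparse single-cell Hi-C
    contact maps. Each intrachromosomal contact matrix is imputed with a
    regularized graph-Laplacian kernel, resized, smoothed with a small Gaussian
    kernel, and passed through a dissipative matrix exponential; per-offset
    superdiagonal band features (z-scored bands and their trinarized
    differences) are compared across cells by cosine distance, reduced by
    nonmetric multidimensional scaling and principal component analysis, and
    spectrally embedded with the random-walk (Shi-Malik) graph Laplacian before
    k-means++ clustering. Includes readers for cooler/scool, 4DN pairs and
    sparse triplet text, the cell and chromosome quality filters customary for
    1 Mb single-cell Hi-C, adjusted Rand index and normalized mutual
    information implementations, a labeled synthetic single-cell Hi-C
    generator, and drivers for hyperparameter sweeps and chromosome-subsampling
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    parallel,
    rhdf5,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
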