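Package: pare
Title: Partial Embeddings for Confounder-Adjusted Dimension Reduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Removes the effects of nuisance covariates (batch, scanner,
    donor, age, ...) from any distance-based dimension reduction method.
    Principal coordinates obtained by classical multidimensional scaling
    are residualized against a nuisance design matrix (adjusted principal
    coordinates analysis), and the adjusted geometry -- either the
    residual coordinates or the covariate-adjusted dissimilarity matrix --
    is handed to t-SNE, UMAP, or any registered embedder, yielding a
    partial embedding (PARE).  Includes the local inverse Simpson's index
    (LISI) and silhouette-width metrics used to evaluate batch mixing and
    group separation in embeddings, and a synthetic-data generator with
    controllable group, batch, and continuous-confounder effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rtsne,
    jsonlite,
    stats,
    utils,
    uwot
Suggests:
    ape,
    cluster,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
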