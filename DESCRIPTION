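Package: cranmod
Title: Modularity and Integration of Cranial Landmark Configurations in
    Wild/Domestic Mammal Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Landmark-based geometric morphometrics toolkit for testing
    tissue-origin (neural crest vs mesoderm) modularity and integration of
    the mammalian cranium across wild/domestic pairs. Implements generalized
    Procrustes superimposition with extraction of the symmetric component of
    shape for object-symmetric configurations, allometric regression of shape
    on log centroid size with residual-randomization (RRPP) significance,
    the covariance-ratio (CR) modularity test, two-block partial least
    squares integration with permutation effect sizes, relative eigenvalue
    standard deviation (eigenvalue dispersion) as an integration magnitude,
    Procrustes-variance disparity with permutation contrasts, and downstream
    ordination and cross-pair comparisons. A synthetic landmark generator
    with known modular covariance, allometry and group effects provides
    ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
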