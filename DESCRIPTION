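Package: epiwalsh
Title: Sparse Walsh-Hadamard Spectral Analysis and Regularization of Fitness Landscapes
Version: 0.1.0
Authors@R: person("epiwalsh", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Analyze and learn sequence-to-fitness maps through their
    Walsh-Hadamard (epistatic) spectrum. Provides exact fast Walsh-Hadamard
    transforms of combinatorial landscapes, a sublinear sparse transform based
    on sparse-graph-code subsampling with a peeling decoder, spectral-l1
    regularized neural-network training, a scalable ADMM variant coupling the
    network to a sparse spectrum at subsampled points, synthetic
    sparse-epistasis landscape simulation, Box-Cox preprocessing, and a Lasso
    baseline over Walsh-Hadamard monomial features with OLS debiasing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
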