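Package: rxnbo
Title: Batch Bayesian Optimization of Reaction Conditions on Constrained Categorical Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Closed-loop optimization of reaction conditions over a finite,
    chemistry-constrained grid of categorical and discretized numeric
    parameters, as used by autonomous (self-driving) laboratories. Provides a
    constraint-aware grid builder for the iodination of terminal alkynes
    (chloramine and N-iodosuccinimide routes), conversion/yield/merit
    objectives from internal-standard calibrated HPLC areas, a greedy
    maximum-coverage initial design, a Gaussian-process surrogate with a
    Matern-5/2 kernel over one-hot encoded parameters, batch expected
    improvement with a constant-liar policy, per-substrate convergence with
    search-space contraction, a synthetic reaction oracle for desk-scale
    benchmarking, and t-SNE contour maps for interpreting the optimizer.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
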