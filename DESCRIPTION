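Package: swarmselect
Title: Two-Stage Multi-Objective Particle Swarm Feature Selection for
    High-Dimensional Small-Sample Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hybrid filter-wrapper feature selection for wide regression
    problems such as metabolomics tables where features vastly outnumber
    samples. Stage one ranks features by minimum-redundancy
    maximum-relevance (mRMR) mutual information (with Pearson and Spearman
    baselines) and adaptively picks a candidate prefix by sequential
    forward search scored with cross-validated partial least squares
    regression. Stage two runs a multi-objective particle swarm optimizer
    with a bounded Pareto archive, crowding-distance truncation, adaptive
    grid leader selection, nonlinearly decreasing inertia weight and
    linearly scheduled acceleration factors, returning a Pareto front that
    trades subset size against prediction error. Includes a synthetic
    data generator with known relevant, redundant and irrelevant features,
    broom-style tidiers, ggplot2 plotting, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
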