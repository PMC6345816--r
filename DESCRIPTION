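Package: multidom
Title: Minimum Dominating Sets for Controlling Multilayer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Driver-node identification for multilayer networks under the
    minimum dominating set (MDS) controllability framework. Computes exact
    single-layer MDSs and multilayer MDSMs by integer linear programming
    (GLPK backend), including a degree-1 preprocessing that fixes part of an
    optimal solution before the solve, the MDSI intersection baseline, and
    union-graph comparisons. Ships the analytic layer-recursion estimators of
    the dominating-set fraction for k-regular and maximally assortative
    scale-free multilayers, perturbation-theory estimates of the MDSM growth
    under degree-preserving rewiring and random edge insertion/deletion, the
    corresponding simulation pipelines, random-graph generators, and a
    functional-class enrichment statistic for control sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: GLPK stand-alone solver (glpsol) on the PATH
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
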