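Package: cloneFate
Title: Event-Driven Simulation of Clonal Dynamics and Early Oncogenesis
    in Epithelial Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Single-cell stochastic model of clonal expansion, senescence
    and rare malignant transformation in a hormonally driven epithelium
    (modelled on the uterine endometrium).  Each cell follows a
    continuous-time trajectory of proliferation potential coupled to a
    programmed differentiation schedule; random mutational effects erode
    the differentiation coefficient, and a cell divides or dies when its
    cycle-status integral reaches +1 or -1.  The package provides an exact
    event-driven branching-process engine (C++ core), lineage phylogeny
    with fractional-mass most-recent-common-ancestor analysis, tumor
    detection at a configurable mass threshold, intra-tumor heterogeneity
    statistics (division-depth, differentiation and proliferation
    distributions, cancer-stem-cell fraction), exact Poisson incidence
    confidence intervals, and a two-sample Kolmogorov-Smirnov comparison
    of tumor cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
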