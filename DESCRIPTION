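Package: plastivec
Title: Multivariate Plasticity and Adaptive Divergence from Reciprocal
    Transplant Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies phenotypic and transcriptomic plasticity for taxa
    reciprocally transplanted along an environmental gradient. Derives leaf
    and physiological traits from raw measurements, fits univariate
    reaction-norm mixed models with genotype-by-site and block random
    effects, tests species-by-elevation interactions by likelihood ratio,
    and summarises multivariate divergence through mean standardisation,
    MANOVA with a genotype-within-cell error stratum, the among-group
    divergence (D) matrix and its leading eigenaxes, and unit-length
    plasticity and divergence vectors compared by angles. Includes
    Kaplan-Meier and proportional-hazards survival analysis with a
    species-by-elevation interaction test, a negative-binomial
    differential-expression layer with a within-species low-count rescue
    filter, reaction-norm quadrant classification, correlation-based
    coexpression modules with eigengene-elevation tests, and Fisher
    gene-ontology enrichment. A synthetic-data generator reproduces the
    statistical structure of a two-species, four-elevation clonal
    transplant design so that every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    emmeans,
    survival,
    MASS,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
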