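Package: fluxsampler
Title: Uniform Sampling of the Steady-State Flux Space of Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Samplers for the steady-state flux polytope of constraint-based
    metabolic models, {v : Sv = 0, lb <= v <= ub}. Implements artificial
    centering hit-and-run (ACHR) with linear-programming warm-up in two chain
    orchestration modes -- long thinned parallel chains (the OptGP scheme) and
    restart-per-sample short chains (the gpSampler scheme of the COBRA
    Toolbox) -- alongside plain hit-and-run and a rejection-sampling oracle
    for low-dimensional validation. Includes flux variability analysis with
    blocked-reaction removal, the xy-deviation measure for comparing sampler
    outputs through sorted bound-normalised chains, and empirical MCMC
    convergence diagnostics (Geweke, multivariate Gelman-Rubin,
    Heidelberger-Welch). Models are read from SBML (Level 3 + FBC),
    cobra-style JSON, or a plain matrix-plus-bounds tabular format.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    boot,
    jsonlite,
    xml2,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'lp.R'
    'model-io.R'
    'polytope.R'
    'warmup.R'
    'samplers.R'
    'deviation.R'
    'diagnostics.R'
    'synthetic.R'
    'cli.R'
    'fluxsampler-package.R'
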