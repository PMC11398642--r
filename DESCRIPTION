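Package: jsdmgibbs
Title: Block-Gibbs Fitting Engine for Hierarchical Joint Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A block-Gibbs sampler for hierarchical joint species distribution
    models (HMSC-style): trait- and phylogeny-structured species regression
    coefficients, latent-factor random levels with non-spatial, full
    Gaussian-process, predictive-process and nearest-neighbour GP structures,
    probit data augmentation for presence-absence data, multi-chain MCMC with
    transient and thinning, convergence diagnostics, a synthetic community
    generator, a language-neutral model/posterior interchange format, and a
    command-line fitting and benchmarking interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    jsonlite,
    parallel,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
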