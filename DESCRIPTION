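Package: floodkin
Title: Escape Kinetics from Flooding-Biased Overdamped Langevin Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating rare-event escape kinetics (drug release
    times and rates) from biased and unbiased overdamped Langevin simulations
    on one-dimensional potential surfaces. Implements a static Gaussian-mixture
    flooding bias and an on-the-fly kernel-density flooding bias with a
    well-tempered target and an excluded (transition-state) region, the
    hyperdynamics-style rescaling of biased simulation time by the mean
    exponentiated bias, exponential fits of exit-time distributions with a
    Kolmogorov-Smirnov check of Poissonian statistics, a two-depth diffusion
    estimator, and an exact quadrature oracle for one-dimensional mean
    first-passage times used as ground truth throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
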