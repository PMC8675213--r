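Package: navclamp
Title: Synthetic Voltage-Clamp Generation, Sodium-Channel Biophysics, and
    Cortical Neuron Simulation for NaV1.1 Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying mixed gain- and loss-of-function variants of
    the neuronal voltage-gated sodium channel NaV1.1 (SCN1A), built around
    the L1624Q epilepsy variant. Provides a phenomenological generator of
    whole-cell voltage-clamp sweep sets with known ground truth under four
    standard protocols (activation, steady-state fast inactivation, recovery
    from inactivation, persistent current); an analysis suite that measures
    peak currents, conductance-voltage curves, Boltzmann fits,
    inactivation-onset time constants, current density, recovery kinetics and
    persistent-current fractions from such sweep sets; genotype x temperature
    interaction ANOVA with additive stepdown and per-voltage contrasts on
    log-transformed time constants; and a single-compartment conductance-based
    cortical pyramidal neuron model with wild-type and variant sodium-current
    parameterizations, persistent sodium current, and excitability metrics
    (rheobase, firing-rate curves, persistent firing after stimulus offset,
    depolarization block under current ramps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    car,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Electrophysiology, Software, Preprocessing, StatisticalMethod
RoxygenNote: 7.3.3
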