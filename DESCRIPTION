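Package: soundgain
Title: Hierarchical Bayesian Ideal-Observer Modelling of Sound-Induced
    Compression of Visual Perceptual Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling how task-irrelevant sounds alter visual
    temporal-frequency discrimination in a rodent two-alternative
    forced-choice task.  Provides calibrated sound-pressure-level
    computation for fixed-amplitude and amplitude-modulated white-noise
    stimuli, a Bayesian ideal-observer psychometric model with a
    sound-intensity-dependent gain factor and lapse rates, a synthetic
    cohort generator emulating the behavioural task, hierarchical
    Bayesian inference of per-animal and population parameters by MCMC,
    Pareto-smoothed importance-sampling leave-one-out model comparison
    validated against exact refitting, and group-level frequentist
    reporting (repeated-measures ANOVA on arcsine-transformed choice
    proportions with post-hoc tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    emmeans,
    yaml,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
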