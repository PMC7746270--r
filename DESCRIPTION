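Package: motionprior
Title: Bayesian Observer Models of Motion Estimation Under Learned Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a visual statistical-learning
    task in which observers estimate the direction of a moving dot stimulus
    whose direction statistics are biased toward two frequent directions.
    Provides the task design (interleaved contrast conditions, n-up/1-down
    luminance staircases, biased direction schedules), Bayesian observer
    models that combine a bimodal learned prior with a von Mises sensory
    likelihood (including prior-based lapses and direction-dependent sensory
    noise variants), non-integrative prior-or-likelihood response-strategy
    models, a synthetic-session generator, behavioral summary statistics
    (von Mises + uniform mixture fits of estimation errors, detection and
    reaction-time summaries, a hallucination probability ratio, windowed
    learning dynamics), maximum-likelihood model fitting with BIC and
    protected-exceedance-probability model comparison, and parameter and
    model recovery harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
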