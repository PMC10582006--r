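Package: rlpower
Title: Reinforcement-Learning Signals in Intracranial Field Potential Power
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying how oscillatory power in deep-brain
    local field potentials encodes reinforcement-learning variables during a
    probabilistic reward/punishment learning task. Provides Q-learning
    behavioral modeling with maximum-likelihood fitting and AIC comparison
    against random responding, multitaper time-frequency decomposition with
    trial-wise normalization and artifact rejection, trial-wise general linear
    models of spectral power on expected values and outcomes, two-level
    cluster-based permutation statistics across recording sites, and
    frequency-band random-effects Bayesian model selection with exceedance
    probabilities. A synthetic-cohort generator produces task behavior and
    epoched field potentials with known ground-truth coupling for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
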