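Package: sdtbandit
Title: Signal Detection Problems as One-Armed Contextual Bandits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recasts the classical normal-normal (and power-law) signal
    detection problem as a one-armed contextual bandit in which a receiver
    must learn, from accepted signallers only, how a continuous cue relates
    to the probability that a signaller is desirable, while exploiting that
    knowledge. Provides generative environments with closed-form optimal
    acceptance thresholds, sequential Bayesian logistic beliefs maintained
    by Laplace (quadratic) approximation, a family of
    exploration-exploitation acceptance policies (Thompson sampling,
    Softmax, Greedy, epsilon-Greedy, UCB, Midpoint, Random, and the
    complete-information SDT threshold), a replicated simulation engine,
    a synthetic-volunteer experiment generator with a trembling-hand
    deviation process, and hierarchical mixture-model fitting by MCMC with
    PSIS-LOO model comparison and model-recovery studies to identify which
    policy generated a choice log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
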