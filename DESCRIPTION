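Package: prosodim
Title: In-Silico Replication Toolkit for Statement-Question Intonation
    Perception and Production Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and scores psychoacoustic experiments on
    statement-question intonation perception and production, of the kind used
    to study prosody processing in autism. Provides a 2-down-1-up adaptive
    staircase for pitch-direction discrimination thresholds with simulated
    Weibull 3AFC observers; synthesis of gliding-tone stimuli, pseudo-utterance
    F0 contours and their odd-harmonic musical analogues; signal-detection
    scoring with the log-linear d-prime correction, response-bias proportions
    and per-individual binomial chance classification; autocorrelation F0
    tracking and signed final-word glide measurement for imitation scoring;
    repeated-measures ANOVA interaction power via the noncentral F
    distribution; and a synthetic-cohort generator with Gaussian-copula
    dependence between pitch thresholds and intonation sensitivity, so the
    full analysis pipeline is exercisable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
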