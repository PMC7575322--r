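Package: monoconn
Title: Monosynaptic Pyramidal-Interneuron Connection Detection from Spike-Time Cross-Correlograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects putative monosynaptic pyramidal cell to interneuron
    connections from extracellular spike trains by locating sharp short-latency
    (0.5-2.5 ms) peaks in 1 ms-binned spike-time cross-correlograms, and
    quantifies session-to-session changes in spike-transmission probability
    after subtracting the chance level estimated from the +/-10-50 ms
    correlogram flanks. Includes readers for Klusters-style .res/.clu spike
    files and a plain tabular interchange, a multi-session Poisson spike-train
    simulator that plants connections with known transmission probabilities
    and optogenetic-style rate modulation, per-session firing-rate and
    relative-change metrics, spike-pairing-event counts, split-half stability
    baselines, and a statistical layer built on linear mixed models with a
    random animal intercept (model comparison, partial correlations, Fisher-Z
    correlation contrasts, rank tests, Holm-Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
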