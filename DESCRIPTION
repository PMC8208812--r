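Package: wmgating
Title: Working-Memory Gating of Stimulation-Evoked Cortical Input Efficacy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of how spatial working memory modulates the efficacy of
    electrically evoked corticocortical input in trial-based primate
    electrophysiology. Detects orthodromically activated units from
    peristimulation firing probabilities, estimates evoked-spike latencies and
    classifies fast (putatively monosynaptic) versus slow input, separates
    antidromically activated units with the collision test, quantifies
    stimulation efficacy (adjusted spike counts, log-ratio response
    magnitudes, evoked latencies) by memory condition, measures
    shuffle-corrected joint spiking of simultaneously recorded pairs, and
    characterizes visual, memory and motor activity with sign-rank tests and
    ROC (area under curve) selectivity in a memory-guided saccade task.
    Includes Hartigan's dip test for latency bimodality and a seeded
    synthetic-session generator emulating the statistical structure of such
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
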