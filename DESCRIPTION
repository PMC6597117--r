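Package: objspace
Title: Memory-Trace Modelling and Analysis for the Object Space Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Object Space Task, a rodent object-place paradigm
    probing cumulative versus single-event spatial memory across three
    conditions (stable, overlapping, random). Generates counterbalanced
    trial schedules for the rat and mouse protocols, implements a family of
    memory-trace learning models (leaky place-object counts with
    entropy-driven softmax exploration, with optional overnight forgetting
    and free initial traces), fits them per session by multi-start maximum
    likelihood with chance comparison, likelihood-ratio tests and AIC/BIC
    model selection, simulates model agents over schedules including
    (alpha, beta) parameter sweeps, and computes the behavioral statistics
    of the task: discrimination indices, exclusion rules, one-sample t
    tests versus chance and repeated-measures ANOVAs. A synthetic-data
    generator produces complete cohorts (schedules, exploration times,
    ground-truth parameters) so that fitting and statistics are testable
    end to end without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
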