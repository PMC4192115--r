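Package: touchPDR
Title: Touchscreen Pairwise Discrimination and Reversal Learning: Simulation, Scoring and Exact Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for touchscreen-based cognitive phenotyping with pairwise visual
    discrimination (PD) and reversal (PDR) tasks. Provides a deterministic task engine
    for the staged training protocol and the PD/PDR trial loop, a constrained
    pseudo-random side scheduler, a reinforcement-learning cohort simulator with
    young/aged parameter sets, per-animal scoring (binomial stimulus-bias screening,
    trials-to-criterion, perseveration by binomial and 50-percent criteria, latency
    summaries), exact tie-aware Mann-Whitney U tests, Spearman rank correlation, and a
    group-comparison report. Ships a per-animal summary table from a published mouse
    lemur aging study as a fixture from which every group statistic can be recomputed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
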