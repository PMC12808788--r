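Package: cuttlemem
Title: Episodic-Like Memory Simulation of Cuttlefish Foraging Behavior
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A parsimonious model of episodic-like memory as a queryable
    three-dimensional value matrix indexed by what (object kind), when
    (hour of day), and where (grid cell), learned with a delta rule and
    read out through softmax action selection. Includes two agent-based
    grid-world experiments: a two-phase foraging task in which a
    cuttlefish agent learns that a preferred prey is only available after
    a delay, and a predator-prey scenario with object-centric ("what")
    and place-centric ("where") memory-query policies. Provides tidy run
    logs, summary statistics for choice percentages and per-day outcome
    rates, expected-value landscape exports for mental-time-travel style
    queries, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
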