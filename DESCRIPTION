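Package: bosgame
Title: Analysis and Simulation of Dyadic Coordination in Transparent
    Bach-or-Stravinsky Games
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dyadic choice behaviour in iterated
    transparent Bach-or-Stravinsky (BoS) coordination games, in which two
    agents repeatedly choose between two colour targets whose sides are
    randomised and can see each other's unfolding reach movements. Provides
    the BoS payoff structure and balanced target-layout schedules, per-trial
    outcome evaluation, choice metrics (fraction of choosing own colour and
    objective left side, average and joint reward), naive mutual-information
    estimation between agents' binary choice series with Whittle surrogate
    significance, the dynamic coordination reward (DCR) statistic with its
    random-play baseline and corner confidence interval, action-time and
    action-visibility analyses (Welch tests, logistic visibility model,
    visibility-following correlation), coordination-switch tallies, and an
    agent-based simulator of dyadic sessions under parametrised strategies
    (fixed colour or side, turn-taking, confederate block alternation,
    leader-follower gated by action-time differences, opaque segments).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
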