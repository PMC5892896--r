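Package: mtcsim
Title: Agent-Based Simulation of Micro-Targeted Election Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-candidate election campaign over a heterogeneous
    electorate in which voters revise their candidate preference through a
    Bayesian source-credibility model of persuasion. One candidate runs a
    micro-targeted campaign that screens voters on belief, perceived
    credibility and turnout propensity; the other broadcasts to voters chosen
    uniformly at random. Provides seeded, reproducible single runs, Monte
    Carlo parameter sweeps over candidate credibility and campaign reach,
    break-even reach-ratio estimation, and ggplot2 visualisations of vote
    share against reach ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    parallel,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
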