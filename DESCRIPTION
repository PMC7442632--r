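Package: apeworld
Title: Agent-Based Virtual-World Simulation of Ape Socioecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, seeded, headless re-implementation of a
    virtual-world model of hominoid socioecology. Twelve avatars forage for
    clumped fruit and dispersed grass, groom, call, nest, and mount
    coalitionary attacks on a fruit-stealing outgroup "pirate" over 35
    ninety-second days, under two feeding-ecology treatments ("chimpanzee":
    abundant fruit, slow grass; "bonobo": scarce fruit, fast grass) that hold
    aggregate food constant. Agent behaviour is supplied through pluggable
    policies; scripted baseline policies generate synthetic sessions. The
    analysis layer computes nesting-proximity series, daily activity
    histograms, coalition-attack tallies, vision-overlap group partitions,
    exact small-sample Mann-Whitney U tests, and OLS trendlines from typed
    event logs, and a command-line interface ties simulation to analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
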