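Package: holosim
Title: Forward-Time Simulation of Host-Associated Microbiome Evolution
    Under Host and Microbial Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based forward-time simulation of host-associated microbial
    communities (microbiomes) evolving in a constant-sized Wright-Fisher host
    population. Offspring assemble their microbiomes from a mixture of parental
    and environmental sources (mixed acquisition), the environmental pool is
    itself a mixture of a fixed reservoir and pooled parental microbiomes
    (mixed environment), and three interacting selection regimes can act on
    top of the neutral assembly process: host selection (microbial traits
    alter host reproductive success), trait-mediated microbial selection
    (universal trait scores alter microbial acquisition), and host-mediated
    microbial selection (heritable, host-lineage-specific trait scores alter
    microbial acquisition). Includes the full summary-statistic suite
    (Shannon alpha/gamma diversity, Bray-Curtis beta diversity, host and
    microbial relative fitness, beneficial/commensal/pathogenic composition,
    host-microbe trait-fitness consistency), parameter-sweep drivers with
    replicate management, enumerable toy worlds with closed-form expectation
    oracles, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
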