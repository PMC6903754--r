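Package: dyadtempo
Title: Temporal Microstructure of Dyadic Agonistic Behavior
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how pairs of animals form
    dominant-subordinate relationships from timestamped behavioral event
    logs. Implements Kleinberg burst detection on agonistic onset series,
    two burst-wise criteria (phi-coefficient and difference method) for
    locating the burst at which a relationship resolves, segmentation of
    sessions into pre-, middle- and post-resolution phases with paired
    phase-wise behavior comparisons, within-individual first-order Markov
    transition tests with quasi-independence expected counts (iterative
    proportional fitting over structural zeros) and no-repeat permutation
    nulls, and a directional timed-window cross-correlation (Forward Spike
    Time Tiling Coefficient) between partners. A synthetic dyad generator
    with planted ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
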