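Package: sinet
Title: Community-Structure Consistency Analysis for Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Sinet", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds binary correlation networks from multi-subject node
    time-series, detects network communities by repeated modularity
    maximization, quantifies per-subject spatial consistency against
    template subnetworks with the scaled-inclusivity statistic, and tests
    whether a continuous covariate is associated with community-structure
    differences using pairwise distance regression with subject fixed
    effects and step-up false-discovery-rate adjustment. Includes a
    synthetic-cohort generator with planted community structure so the
    full pipeline is testable without imaging data, plus
    framewise-displacement/DVARS motion scrubbing, band-pass filtering,
    and confound regression for the signal-cleaning stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
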