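Package: hubspoke
Title: Capacity-Constrained Hub-and-Spoke Allocation for Territorial Health Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Travel-time-based assignment of municipalities to predefined
    hub and spoke service nodes under population capacity caps. Parses
    origin-destination road travel-time matrices (ISTAT dialect),
    municipal demographics and node rosters into a validated territory;
    runs a multi-phase proximity-first allocation heuristic with
    iterative cap-compliant reallocation; computes per-node and network
    accessibility statistics and multi-threshold scenario tables; and
    ships a seeded synthetic-territory generator emulating a sparse
    mountainous province so the whole pipeline is testable without
    external downloads. Includes an exhaustive exact allocator for small
    instances used as a validation oracle, and a command-line interface
    for allocation, scenario comparison and simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
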