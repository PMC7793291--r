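Package: paretopaths
Title: Multiobjective Least-Cost Paths for Habitat Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models inter-habitat movement corridors on attributed landscape
    networks as a three-objective least-cost path problem (traversal risk,
    moisture-weighted distance, elevation change) and enumerates its
    Pareto-optimal solutions. Provides ecological arc-cost derivation from
    elevation, topographic wetness and land cover; a deterministic weighted-sum
    shortest-path solver; biobjective non-inferior set estimation (NISE) and its
    three-objective extension (MONISE) for all supported efficient solutions; a
    multi-criteria label-correcting algorithm for the complete efficient set
    (supported and unsupported); dominance filtering and convex-envelope
    classification utilities; seeded synthetic-landscape generators; and CSV
    input/output with per-wetland and per-arc reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
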