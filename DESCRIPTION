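Package: flysin
Title: Social Interaction Networks from Walking-Fly Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts per-frame trajectories of groups of walking flies
    (Drosophila) into weighted social interaction networks (SINs) using a
    distance/duration proximity criterion (two body lengths for at least
    half a second), computes local (centrality, clustering), global
    (density, path length, efficiency, heterogeneity, assortativity) and
    middle-level (Louvain communities, modularity, components) network
    measures, and compares populations of networks with Welch-corrected
    t-tests. Includes a seeded arena simulator with controllable sociality
    (thigmotaxis, attraction, immobile individuals) so the whole pipeline
    can be exercised without video tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    xml2,
    yaml,
    MASS,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
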