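Package: parkflux
Title: Park Exposure Networks from Urban Mobility Trajectories
Version: 0.1.0
Authors@R:
    person("parkflux", "developers", email = "parkflux@example.org", role = c("aut", "cre"))
Description: Builds weighted bipartite census-tract/park exposure networks from
    daily mobility trajectories, park polygons and tract demographics. Provides
    OSM-style park tag filtering and overlap merging, buffer-based exposure
    assignment (uncertainty circle around each activity), tract and park
    strengths (exposure and demand), weighted neighbor averages, predominant
    racial/ethnic group labeling, homophily, Barber bipartite modularity with
    leading-eigenvector community detection, mutual-information permutation
    tests, log-binned densities and log-normal fits, and a seedable synthetic
    city generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
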