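Package: exporoute
Title: Exposure-Adjusted Cycle Routing and Population-Level Multi-Exposure Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Least-cost cycle routing on street networks with an environmental
    impedance function that penalises edges by air-pollution (AQI), noise (Lden)
    or rewards greenery (GVI), a sensitivity sweep producing detour-constrained
    exposure-optimal alternatives to the shortest route, trip-weighted
    aggregation of route exposures to bike-share station Voronoi catchments,
    and multi-exposure route-similarity analysis (5 m buffer overlap and
    Pearson correlation of route-mean exposures). Includes a synthetic-city
    generator (jittered grid network, correlated Gaussian exposure fields,
    gravity-model trips) so the whole pipeline runs end-to-end without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    polyclip,
    deldir,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
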