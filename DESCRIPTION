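Package: refnet
Title: Travel-Time Network Analysis for Rural Emergency Referral Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multimodal (road, fixed-route vehicle, boat, walk) travel-time
    networks for rural health-facility access, performs closest-facility routing
    from village centroids via transport hubs, delineates 30/50-minute
    rickshaw-based catchment zones around subdistrict hospitals, and tabulates
    referral-call compliance and transport-uptake statistics stratified by zone
    and semester. Includes seeded generators for study-shaped synthetic
    geography and call logs so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
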