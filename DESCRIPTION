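Package: imtn
Title: Daily Intermunicipal Travel Networks from Device Location Pings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs and analyses daily intermunicipal origin-destination
    travel networks from anonymized device-location pings. Edge weights are
    the fraction of the day's observed device panel moving between two
    localities, with metropolitan zones collapsed to single nodes. Includes a
    seeded gravity-model mobility simulator for fully reproducible synthetic
    studies; global (total edge weight), local (degree, strength, betweenness
    centrality time series, coefficients of variation, rank turnover) and
    mesoscale (label-propagation community dynamics) analyses; heavy-tailed
    strength-distribution diagnostics (log-normality tests, excess kurtosis,
    Beta Rank Function rank-size fits); and an end-to-end pipeline with a
    reproducible manifest.
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
    tools,
    utils,
    yaml
Suggests:
    arrow,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
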