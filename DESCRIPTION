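Package: bcfuse
Title: Spatiotemporal Fusion of Mobile Monitoring and Fixed-Site Sensor
    Networks for Black Carbon Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses time-averaged, spatially dense multipollutant maps from
    repeated mobile monitoring with temporally complete, spatially sparse
    black-carbon (BC) time series from a fixed low-cost sensor network.
    Paired non-negative matrix factorizations decompose the
    pollutant-by-location and site-by-time systems into shared latent
    spatial patterns; a least-squares reprojection through a binary
    sampling matrix and a Moore-Penrose pseudoinverse links the two
    factorizations and reconstructs a spatiotemporally complete BC
    concentration field. Includes drive-log aggregation to
    median-of-drive-pass-mean segment maps, sensor binning and gap
    imputation, ordinary kriging of segment maps to sensor sites,
    knee-point factorization rank selection, Lagrangian and leave-site-out
    evaluation protocols, pivoted-QR sensor placement, and a
    synthetic-scene generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
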