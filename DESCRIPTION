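Package: dendrotrips
Title: Response Functions of Gap-Junction Coupled Dendritic Trees via Sum-Over-Trips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Green's function (response function) of networks of
    branched dendritic trees coupled by dendro-dendritic gap junctions, for
    passive ('RC') or resonant quasi-active ('LRC') membrane, using the
    sum-over-trips path expansion on the extended tree structure. Provides
    frequency-domain kernels, exhaustive trip enumeration with adaptive
    length truncation, compact closed-form two-cell solutions (including a
    geometric word-series resummation for two soma-and-dendrites cells),
    numerical inverse Laplace transforms, stimulus responses (impulse,
    rectangular pulse, chirp), preferred-frequency analysis, and a
    boundary-condition residual suite for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
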