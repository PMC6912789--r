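Package: agonet
Title: Dominance Indices and Social-Network Centralities from Agonistic
    Interaction Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-stamped agonistic-interaction event
    logs from group-housed animals (pigs after rehousing and mixing).
    Computes two dyadic dominance indices, builds initiator-receiver and
    winner-loser directed networks, and derives degree, closeness and
    betweenness centralities on rising cumulative time windows. Provides
    Spearman rank concordance series between indices and centralities,
    an analysis of absolute differences between subsequent rank positions
    with Holm-adjusted contrasts, and partial least squares path modelling
    (Mode A, path weighting) with bootstrap inference to quantify how well
    centrality blocks explain latent dominance. Includes a calibrated
    synthetic event-log generator with known ground-truth dominance so the
    entire pipeline can be exercised and validated without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
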