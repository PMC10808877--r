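Package: envcorridors
Title: Environmental Barriers to Cultural Transmission on Gridded Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies environmental and travel barriers between societies by
    start-relative least-cost paths over climate principal-component surfaces,
    models pairwise cultural sharing with crossed society random intercepts
    while controlling for shared ancestry and neighbourhood transmission, and
    compares barrier magnitudes around centres of agricultural origin with
    variance-weighted models, spatial eigenvector filtering and Tukey
    contrasts. Includes a synthetic-world generator (climate, terrain,
    societies, language tree, trait histories) so the whole pipeline is
    testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
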