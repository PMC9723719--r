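Package: ecocycle
Title: Seasonality and Environmental Coupling of Marine Microbial Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multiannual 16S rRNA amplicon time series
    of marine bacterioplankton, centred on the SAR11 (Pelagibacterales)
    ecotypes. Provides ecotype-level aggregation and rarefaction of ASV count
    tables, Bray-Curtis time-decay curves with periodic spline fits, Fisher
    g-test periodicity screening with harmonic-regression classification of
    ASVs into summer- and winter-peaking guilds, constrained ordination
    (db-RDA) and PERMANOVA of community dissimilarities on environmental
    variables, warm/cold hierarchical clustering, and Morlet wavelet
    coherence between weekly community turnover and environmental change
    with coupled/uncoupled phase segmentation. Includes a synthetic-data
    generator emulating monthly open-ocean and weekly coastal sampling
    designs so every stage is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    vegan,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    biomformat,
    yaml,
    ggplot2
Config/testthat/edition: 3
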