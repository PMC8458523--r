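Package: whalesong
Title: Structure, Similarity and Seasonal Presence of Humpback Whale Song
Version: 0.1.0
Authors@R:
    person("Avery", "Lindqvist", email = "avery.lindqvist@posteo.net",
           role = c("aut", "cre"))
Description: Tools for analysing the hierarchical structure of humpback whale
    (Megaptera novaeangliae) song from passive acoustic monitoring
    annotations. Classifies annotated hours into social-call, preliminary-song
    and complex-song categories, attributes recordings to presumed individual
    singers, segments song sessions and songs, and computes length and
    complexity measures. Repertoire similarity uses the Dice Coincidence
    Index; theme-sequence similarity uses a token-level Levenshtein similarity
    index with set-median string selection. Similarity matrices are clustered
    by single linkage with multiscale-bootstrap approximately-unbiased (AU)
    support and Newick export. Daily sea-ice concentration series around
    recording stations are summarised with 15 percent edge-crossing events and
    song/ice timing lags. A seeded synthetic-data generator emulates the
    statistical structure of an Antarctic feeding-ground study (two song
    groups, era drift, austral-autumn song peak, sinusoidal ice cycle,
    separable unit-feature clusters), so the full pipeline is testable without
    audio data. A transcription of the study's set-median theme-sequence table
    ships as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
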