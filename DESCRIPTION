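Package: unzipr
Title: DNA Unzipping Force Spectroscopy Analysis of Protein Roadblocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-molecule DNA unzipping experiments that map
    protein roadblocks to translocating motors, as in optical-trap assays of
    CRISPR dCas complexes blocking RNA polymerase or the Mfd translocase.
    Provides nearest-neighbor equilibrium unzipping theory curves, freely
    jointed chain and worm-like chain force-extension relations, conversion of
    raw force-extension traces to base pairs unzipped with baseline alignment
    and interaction peak calling, classification of traces into collision
    outcome categories, a conditional-probability estimator of roadblock
    read-through and removal efficiencies with per-chamber aggregation, and a
    synthetic-data generator that emulates the experiment end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
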