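Package: drgmeta
Title: Cross-Study Integration of Rodent DRG Nerve-Injury Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates per-comparison differential-expression tables from
    rodent dorsal root ganglion (DRG) peripheral nerve injury studies.
    Implements pi-value (significance x fold-change) gene ranking, vote-based
    robust differentially-expressed-gene (DEG) calling with Atf3 timepoint
    gating, ortholog cluster classification and species-preference screening
    between mouse and rat, fuzzy c-means clustering of time-series expression
    with cross-dataset cluster correspondence, Y-chromosome-marker sex
    inference and sex-dimorphism partitioning of injury responses. Ships a
    synthetic-data generator with planted ground truth so every stage of the
    pipeline is testable without any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
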