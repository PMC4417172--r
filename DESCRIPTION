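Package: pausekit
Title: Analysis of Promoter-Proximal RNA Polymerase II Pausing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping and quantifying promoter-proximal RNA
    polymerase II pausing. Calls refined transcription start sites and pause
    positions from paired-end short capped RNA reads, computes fragment-center
    metagene profiles and twin promoter peaks from paired-end Pol II ChIP
    fragments, quantifies permanganate footprint lane profiles with
    bubble-fraction calibration and fractional-occupancy bounds, and estimates
    pause half-lives from initiation-block decay time courses. A seeded
    synthetic-data module generates every input the pipeline consumes, with
    realistic positional structure (initiator-like start-site jitter, 33-35 nt
    pause offsets, divergent antisense transcription, sonication shear bias),
    so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
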