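Package: tstructseq
Title: Targeted Structure-Seq Analysis of RNA Secondary Structure In Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted DMS (dimethyl sulfate) chemical
    probing of RNA structure read out by reverse-transcription termination
    sequencing. Converts aligned RT-stop reads into per-base termination and
    read-through counts, estimates per-base DMS reactivity with an untreated
    control, scans transcripts for thermodynamically stable regions with a
    sliding-window z-score, builds DMS-constrained minimum-free-energy
    secondary-structure models with bootstrap support, and scores base-pair
    conservation, consistent and compensatory mutations over multiple
    sequence alignments. Includes a synthetic-experiment simulator with
    planted structures so the whole pipeline can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
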