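Package: seqscreen
Title: Read Triage, Indel Target Extraction, Variant Filtering and
    Microbial Screening for Short-Read Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the bespoke computational stages of a modular
    short-read DNA analysis pipeline as a self-contained library and
    command-line tool: triage of soft-clipped and unmapped reads for
    realignment and the merge of refined alignments; CIGAR-walk
    extraction of indel-evidenced reference positions into padded BED
    target regions for an intensive indel caller; hard filtering of
    variant calls on genotype quality and depth with region
    restriction; a computational-subtraction microbe screen with
    per-genome read counts and breadth-of-coverage statistics; and
    precision/sensitivity/F-measure benchmarking of call sets against a
    truth set. A synthetic-fixture generator with machine-readable
    planted truth makes every stage testable without external aligners,
    callers or reference downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
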