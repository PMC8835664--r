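Package: lgtscan
Title: Detection of Bacterial-Human Lateral Gene Transfer from Paired-End RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for detecting bacterial-human lateral
    gene transfer (LGT) from paired-end RNA sequencing data. Read pairs are
    aligned to a host reference with a built-in seed-and-extend local aligner,
    half-mapped pairs are realigned to bacterial references, and pairs with
    one mate mapping exclusively to the host and the other exclusively to a
    bacterial reference are called as LGT-supporting. A filtering cascade
    (alignment coverage, low-complexity reads, repeat-region overlap,
    duplicate-junction removal) yields unique LGT events, which are annotated
    against a gene model, aggregated into per-genus count matrices, used to
    stratify samples by multidimensional scaling, and associated with survival
    and categorical clinical markers. A seeded synthetic-cohort generator with
    planted ground truth drives testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    survival,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
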