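Package: tsscan
Title: Transcription Start Site Annotation from DNA Sequence and
    Strand-Specific RNA-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide annotation of transcription start sites (TSSs) by a
    dual-branch convolutional classifier that reads a 1001-bp one-hot DNA
    window together with the matched strand-specific RNA-seq coverage
    vector. Provides balanced dataset construction with shift augmentation
    and distance-constrained negative sampling, hard-negative ("circular")
    retraining that harvests false positives from genome scans, Reptile
    meta-learning across cell types with per-cell-type fine-tuning, fast
    stride-1 scanning of expressed regions, score-track clustering into TSS
    calls, tolerance-based evaluation metrics, convolution-filter motif-gain
    extraction with MEME-format export, and a deterministic synthetic
    fixture generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
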