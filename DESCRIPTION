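Package: pairstitch
Title: Merging Overlapping Paired-End Reads with Empirical Quality-Score
    Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Merges Illumina paired-end reads whose 3' ends overlap into
    single reads spanning the original DNA fragment, by exhaustive gapless
    alignment that also detects dovetailed configurations (fragments
    shorter than the read length, with adapter read-through).  Provides an
    adapter-removal mode that clips 3' overhangs, pluggable models for the
    merged base's quality score (empirical match/mismatch matrices,
    difference-based, and sum-based schemes), a training pipeline that
    derives empirical quality matrices from truth-annotated reads via
    local regression of observed error rates, per-quality-score error
    statistics from SAM alignments, and a quality-aware paired-read
    simulator with correlated first-strand errors for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    data.table,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
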