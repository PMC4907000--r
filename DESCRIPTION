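Package: clonkit
Title: Clonotype Table Analysis for Immune Repertoire Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses clonotype abundance tables produced by common Rep-Seq
    post-processing tools (MiTCR, MIGEC, MiXCR, IgBlast/AIRR, IMGT
    HighV-QUEST, ImmunoSEQ) into a concise internal tab-delimited format and
    computes the standard single- and multi-sample repertoire summaries:
    CDR3 spectratypes, V/J segment usage, clonality breakdowns, analytic
    rarefaction with Chao1 extrapolation, the Efron-Thisted unseen-species
    estimate of total diversity, three clonotype error-correction strategies
    (quality filtering, frequency-ratio merging, replicate intersection),
    flexible clonotype matching and multi-sample joining for public-clonotype
    detection and cross-sample contamination screening, plus a seeded
    synthetic repertoire generator and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
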