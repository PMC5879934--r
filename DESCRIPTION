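Package: damidflow
Title: DamID-Seq Signal Processing, FDR Peak Calling and Binding-Dynamics
    Analysis on GATC Fragments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for DamID-seq experiments profiling
    transcription-factor binding in Drosophila germline tissue. Builds the
    GATC-fragment coordinate system from a genome, converts Dam-fusion
    versus Dam-alone fragment counts into signed -log10 Fisher exact test
    signal tracks, calibrates an empirical false discovery rate from
    biological-replicate noise, and calls enrichment peaks with compound
    significance and ratio criteria. Downstream modules annotate peaks
    against gene models (promoter/UTR/CDS/intron categories, TSS distance
    distributions, averaged TSS profiles, peak-set colocalization and
    intersection), classify direct versus indirect targets by integrating
    mutant differential-expression tables, group transcripts by
    cross-genotype binding dynamics at transcription start sites, and call
    tissue-specific transcripts from a tissue-by-transcript expression
    ratio matrix. A synthetic-data module generates complete pipeline
    inputs with planted ground truth for validation, and a pipeline driver
    orchestrates the stages with a checksummed run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
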