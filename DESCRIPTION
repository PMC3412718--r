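Package: regulonSMS
Title: Regulon Reconstruction by Phylogenetic Footprinting and Similar
    Motif Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative reconstruction of bacterial transcription-factor
    regulons, modelled on the nitrogen regulators GlnR and TnrA of low-GC
    Gram-positive bacteria. Builds family-specific position frequency
    matrices by phylogenetic footprinting of orthologous upstream regions
    anchored at a conserved palindromic site near the promoter -35 element,
    scores candidate binding sites with the Similar Motif Scoring (SMS)
    statistic, predicts regulon membership under relative-similarity and
    upstream-distance criteria (operon- and divergon-aware), groups
    homology hits into ortholog families by an e-value-gap rule, and
    aggregates cross-species presence/absence and conservation reports.
    Includes a synthetic-genome generator with planted sites so every
    stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'genome-io.R'
    'motif-builder.R'
    'sms-scanner.R'
    'ortholog-cluster.R'
    'regulon-predict.R'
    'synthetic-data.R'
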