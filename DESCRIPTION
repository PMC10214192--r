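Package: splicescreen
Title: Discovery of Alternative-Splicing-Derived Immunotherapy Targets
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens tumor splicing profiles against a multi-tissue reference
    panel to discover alternative-splicing-derived immunotherapy targets.
    Reads rMATS-style event tables and STAR-style splice-junction counts into
    an indexed reference panel of percent-spliced-in (PSI) values and junction
    read counts; runs PSI-based tumor-association, CPM-based secondary,
    junction presence/absence tumor-specificity, and tumor-recurrence screens;
    translates junctions of tumor-enriched isoforms into peptides using
    annotated reading frames; enumerates HLA class I epitope candidates and
    calls TCR targets by median IC50 through a pluggable affinity-predictor
    contract; maps peptides to extracellular domains for CAR-T candidacy;
    and cross-references predicted epitopes against mass-spectrometry
    immunopeptidomics peptide lists. Ships a deterministic synthetic-data
    generator (reference panels with planted tumor events, toy genomes with
    known junction peptides) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    digest,
    matrixStats,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
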