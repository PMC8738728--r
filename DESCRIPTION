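Package: splicecraft
Title: Characterization of Splice-Disrupting and Missense Variants from
    RNA-Seq Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies aberrant splicing (percent spliced in, intron
    retention, allele-balanced transcript partitioning) from splice-junction
    counts and per-base coverage, derives RNA- and protein-level HGVS
    consequences (exon skipping, intron retention, single-nucleotide
    changes) on coding transcript models, combines ACMG evidence codes into
    five-tier classifications with both the point-based and the rule-based
    combiner, and tests spatial clustering of missense variants on protein
    structures with a bootstrap resampling test. Includes simulators for
    toy transcripts, junction/coverage evidence, missense tables and
    residue coordinates so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'acmg-engine.R'
    'transcript-model.R'
    'hgvs-consequence.R'
    'missense-domain.R'
    'utils.R'
    'splice-quant.R'
    'transcript-io.R'
    'synthetic-data.R'
    'run-report.R'
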