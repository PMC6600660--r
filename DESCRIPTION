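Package: microexon
Title: Micro-Exon Discovery, Quantification and Conservation Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of micro-exons (3-51 nt exons) in annotated
    genomes: extraction and classification of micro-exons from GFF3/FASTA
    annotation, detection of candidate internal micro-exons from spliced SAM
    alignments, percent-spliced-in (PSI) quantification from junction-spanning
    reads with replicate merging and constitutive/alternative splicing
    classification, phylostratigraphic gene-age assignment from filtered
    homology hit tables, and micro-exon conservation scoring across collinear
    gene pairs. Ships a deterministic synthetic-data generator (toy genomes,
    annotations with planted micro-exons, spliced reads at known inclusion
    levels, homology tables, collinear partners) so every stage is testable
    against known ground truth, plus a pipeline driver with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
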