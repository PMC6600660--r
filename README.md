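# microexon

Genome-wide analysis of **micro-exons** — exons of 3–51 nucleotides — in
annotated genomes. Micro-exons are short enough to be missed by annotation
and by standard read alignment, yet their inclusion is often regulated and
frame-sensitive: skipping an exon whose length is not a multiple of three
shifts the downstream reading frame. The package is aimed at plant (or any
compact-genome) transcriptomics work where the questions are: *which exons
are micro-exons, are they actually used, how constitutively are they
spliced, how old are their genes, and are they conserved in related
genomes?*

## What it computes

* **Extraction** (`load_annotation`, `extract_annotated_microexons`) —
  parse GFF3 + FASTA into gene models and pull every exon of 3–51 nt, with
  positional class (first/internal/last/single), coding status
  (cds/utr/mixed) and frame class (in-frame iff length ≡ 0 mod 3).
* **Detection** (`scan_alignments`, `call_candidates`) — find internal
  micro-exons as middle blocks of multi-gap spliced SAM alignments
  (anchors ≥ 6 nt, < 2 mismatches), pool support across samples, call
  candidates with > 10 supporting reads, and classify them as annotated /
  novel-in-gene / novel-intergenic.
* **PSI quantification** (`build_junction_library`,
  `count_junction_reads`, `compute_psi`, `merge_replicates`,
  `classify_splicing`, `tissue_expression_sets`) — count reads on
  inclusion/exclusion junction references (100-nt mature-transcript
  flanks, 3-nt overhang) and estimate percent-spliced-in as

      R_tot = 2 * min(R_L, R_R);      PSI = R_tot / (R_tot + R_skipped)

  with a coverage-missingness rule (R_L + R_R ≥ 10 or R_skipped ≥ 10),
  replicate merging (mean if |Δ| < 0.10, else missing), and CS
  (PSI ≥ 0.9) / AS (0.1 ≤ PSI < 0.9) classes.
* **Gene age** (`read_homology_hits`, `filter_hits`,
  `assign_phylostratum`, `age_summaries`) — phylostratigraphy over 13
  nested database levels (filters e ≤ 1e-5, identity ≥ 0.3,
  coverage ≥ 0.8; oldest passing level wins; no hit ⇒ PS13), with
  old (PS1–3) / young (PS11–13) classes.
* **Conservation** (`assess_conservation`, `conservation_summary`) — a
  coding micro-exon is conserved in a collinear partner gene when the
  homologous span (located via global protein alignment) has the same CDS
  phase and length; substitutions are counted on the back-mapped CDS, and
  exon-merge events and domain consistency are reported.
* **Synthetic data** (`sim_config`, `simulate_genome_annotation`,
  `simulate_junction_reads`, `simulate_hit_tables`,
  `simulate_collinear_partner`) — deterministic toy genomes with planted
  micro-exons, spliced reads at known PSI, homology tables with planted
  ages, and edited collinear partners, so every stage is testable against
  ground truth.
* **Pipeline** (`run_pipeline`, `report_summaries`, `mex_cli`) — one
  driver with threshold validation, per-stage outputs, a JSON manifest
  with checksums, and a plain-text summary report. A CLI script is
  installed under `inst/cli/mex`.

## Worked example

```r
library(microexon)
library(data.table)

cfg  <- sim_config(seed = 7, n_genes = 12, depth = 60)
sim  <- simulate_genome_annotation(cfg)
mexs <- extract_annotated_microexons(sim$genes)
refs <- build_junction_library(mexs, sim$genes)
reads <- simulate_junction_reads(sim, refs = refs)
cnt  <- count_junction_reads(reads$library["T1_c1_r1"], refs)
merge(compute_psi(cnt), sim$truth[, .(mex_id, true_psi)], by = "mex_id")[
  1:5, .(mex_id, R_L, R_R, R_skipped, psi = round(psi, 3), true_psi = round(true_psi, 3))]
```

```
                 mex_id   R_L   R_R R_skipped   psi true_psi
1:  G001:chr1:1505-1524    23    22        15 0.746    0.733
2:  G002:chr1:3220-3231    29    29         2 0.967    0.950
3:  G003:chr1:4367-4400    22    21        17 0.712    0.765
4:  G004:chr1:8148-8168    25    24        11 0.814    0.921
5:  G005:chr1:9891-9907    30    29         1 0.983    0.987
```

Each row is one micro-exon in one sample: `R_L`/`R_R` are reads on the two
inclusion junctions, `R_skipped` reads on the skipping junction, and `psi`
the estimated inclusion level, which tracks the planted `true_psi` (rows 2
and 5 are constitutively spliced, row 3 alternatively). Detection on the
same fixture recovers all 12 planted micro-exons, including the one left
out of the GFF3, which comes back as `novel_in_gene`.

## Documentation

`vignettes/microexon-methods.Rmd` describes the models and assumptions,
every tunable threshold with its default and rationale, what the synthetic
generator does and does not emulate, numerical edge-case choices, and
known limitations.
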