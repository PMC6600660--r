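test_that("config validation rejects out-of-domain values", {
  expect_error(sim_config(microexon_length_set = c(3, 52)), "\\[3,51\\]")
  expect_error(sim_config(read_length = 10, min_anchor = 6), "read_length")
  expect_error(sim_config(frame_shift_fraction = 1.2), "\\[0,1\\]")
  expect_error(sim_config(intron_range = c(500, 60)), "intron_range")
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 7, n_genes = 6)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_sim(simulate_genome_annotation(cfg), d1)
  p2 <- write_sim(simulate_genome_annotation(cfg), d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
})

test_that("planted micro-exons appear in the GFF3 unless flagged unannotated", {
  sim <- shared_sim()
  d <- tempfile()
  paths <- write_sim(sim, d)
  genes <- load_annotation(paths[["gff3"]], paths[["fasta"]])
  mexs <- extract_annotated_microexons(genes)
  ann <- sim$truth[annotated == TRUE]
  nov <- sim$truth[annotated == FALSE]
  expect_true(all(ann$mex_id %in% mexs$mex_id))
  expect_false(any(nov$mex_id %in% mexs$mex_id))
  expect_gt(nrow(nov), 0L)
  # structural properties of the annotation
  expect_true(all(sim$truth$length_nt >= 3L & sim$truth$length_nt <= 51L))
  expect_setequal(unique(sim$genes$genes$strand), c("+", "-"))
})

test_that("introns are canonical GT..AG on the annotated strand", {
  sim <- shared_sim()
  ex <- sim$genes_true$exons
  for (tid in unique(ex$transcript_id)[1:4]) {
    e <- ex[transcript_id == tid][order(start)]
    strand <- e$strand[1]; chrom <- e$chrom[1]
    for (i in seq_len(nrow(e) - 1L)) {
      intron <- as.character(Biostrings::subseq(sim$genome[[chrom]],
                                                e$end[i] + 1L, e$start[i + 1L] - 1L))
      if (strand == "-")
        intron <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(intron)))
      expect_equal(substr(intron, 1, 2), "GT")
      expect_equal(substr(intron, nchar(intron) - 1, nchar(intron)), "AG")
    }
  }
})

test_that("emitted SAM records validate against their reference", {
  sim <- shared_sim()
  set.seed(5)
  reads <- simulate_junction_reads(sim, depth = 10L,
                                   design = data.table(sample_id = "s1",
                                                       tissue = "T1", replicate = 1L))
  aln <- reads$genome[["s1"]]
  blocks <- microexon:::cigar_ref_blocks(aln$cigar, aln$pos)
  for (i in seq_len(min(nrow(aln), 50L))) {
    b <- blocks[[i]]
    ref <- paste(vapply(seq_len(nrow(b)), function(j)
      as.character(Biostrings::subseq(sim$genome[[aln$rname[i]]], b[j, 1], b[j, 2])), ""),
      collapse = "")
    expect_identical(aln$seq[i], ref)
    expect_true(all(diff(b[, 1]) > 0))
  }
  # library reads match their reference sequences too
  lib <- reads$library[["s1"]]
  refs <- reads$refs
  for (i in seq_len(min(nrow(lib), 30L))) {
    rn <- lib$rname[i]
    mexid <- sub("\\|(incl|excl)$", "", rn)
    rseq <- if (grepl("incl$", rn)) refs[mex_id == mexid, inclusion_seq]
            else refs[mex_id == mexid, exclusion_seq]
    expect_identical(lib$seq[i], substring(rseq, lib$pos[i], lib$pos[i] + nchar(lib$seq[i]) - 1L))
  }
})

test_that("psi boundary values produce one-sided junction evidence", {
  cfg <- sim_config(seed = 9, n_genes = 4, novel_fraction = 0, true_psi = c(1, 0),
                    replicate_noise_sd = 0, depth = 40L)
  sim <- simulate_genome_annotation(cfg)
  mexs <- extract_annotated_microexons(sim$genes)
  refs <- build_junction_library(mexs, sim$genes)
  reads <- simulate_junction_reads(sim, refs = refs,
                                   design = data.table(sample_id = "s1",
                                                       tissue = "T1", replicate = 1L))
  cnt <- count_junction_reads(list(s1 = reads$library[["s1"]]), refs)
  m <- merge(cnt, sim$truth[, .(mex_id, true_psi)], by = "mex_id")
  expect_true(all(m[true_psi == 1, R_skipped] == 0L))
  expect_true(all(m[true_psi == 0, R_L + R_R] == 0L))
})

test_that("empirical inclusion fraction sits in the binomial 99% interval", {
  cfg <- sim_config(seed = 13, n_genes = 2, novel_fraction = 0, true_psi = 0.8,
                    replicate_noise_sd = 0, depth = 200L)
  sim <- simulate_genome_annotation(cfg)
  reads <- simulate_junction_reads(sim, what = "genome",
                                   design = data.table(sample_id = "s1",
                                                       tissue = "T1", replicate = 1L))
  aln <- reads$genome[["s1"]]
  for (g in sim$truth$gene_id) {
    n_inc <- sum(grepl(paste0("^", g, ":.*:inc"), aln$qname))
    ci <- stats::qbinom(c(0.005, 0.995), 200L, 0.8)
    expect_gte(n_inc, ci[1])
    expect_lte(n_inc, ci[2])
  }
})

test_that("hit-table construction plants decoys failing exactly one filter", {
  sim <- shared_sim()
  tabs <- simulate_hit_tables(sim)
  filt <- filter_hits(tabs$hits)
  # every decoy (older than planted level) fails exactly one of the filters
  truth <- sim$truth[, .(gene_id, ps_level)]
  decoys <- merge(tabs$hits, truth, by.x = "query_id", by.y = "gene_id")
  decoys <- decoys[db_level < ps_level]
  if (nrow(decoys)) {
    fails <- with(decoys, (evalue > 1e-5) + (identity < 0.3) + (coverage < 0.8))
    expect_true(all(fails == 1L))
  }
  got <- assign_phylostratum(sort(truth$gene_id), filt)
  expect_equal(got$ps, truth[order(gene_id), ps_level])
})

test_that("partner rebuild without edits reproduces verdict truth en masse", {
  sim <- shared_sim()
  sp <- simulate_collinear_partner(sim)
  expect_equal(unique(sp$expected$verdict), "conserved_identical")
  expect_equal(nrow(sp$pairs), sim$cfg$n_genes)
  # partner genome is deterministic too
  sp2 <- simulate_collinear_partner(sim)
  expect_identical(as.character(sp$partner$genome), as.character(sp2$partner$genome))
})
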