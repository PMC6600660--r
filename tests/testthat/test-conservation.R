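sim_cons <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_genome_annotation(
        sim_config(seed = 31, n_genes = 8, novel_fraction = 0))
    cache
  }
})

test_that("self-pair yields conserved_identical everywhere (symmetry)", {
  sim <- sim_cons()
  mexs <- extract_annotated_microexons(sim$genes)
  sp <- simulate_collinear_partner(sim)     # no edits
  recs <- assess_conservation(mexs, sp$pairs, sim$genes, sp$partner$genes,
                              species = "self")
  expect_equal(nrow(recs), nrow(mexs[coding_status == "cds"]))
  expect_true(all(recs$verdict == "conserved_identical"))
  expect_true(all(recs$n_substitutions == 0L))
  expect_true(all(recs$phase_a == recs$phase_b))
  expect_true(all(recs$len_a == recs$len_b))
})

test_that("planted substitutions and merges are recovered exactly", {
  sim <- sim_cons()
  mexs <- extract_annotated_microexons(sim$genes)
  edits <- data.table(gene_id = c("G002", "G003", "G005", "G007"),
                      n_subs = c(2L, 1L, 5L, 0L),
                      merge = c(FALSE, FALSE, FALSE, TRUE))
  sp <- simulate_collinear_partner(sim, edits)
  recs <- assess_conservation(mexs, sp$pairs, sim$genes, sp$partner$genes,
                              species = "edited")
  m <- merge(recs, sp$expected, by.x = "gene_a", by.y = "gene_id",
             suffixes = c("", ".exp"))
  expect_equal(m$verdict, m$verdict.exp)
  expect_equal(m$n_substitutions, m$n_substitutions.exp)
  expect_true(all(m[merged == TRUE, exon_merged]))
})

test_that("monotone degradation: k substitutions give n_substitutions = k", {
  sim <- sim_cons()
  mexs <- extract_annotated_microexons(sim$genes)
  g <- "G001"
  max_k <- min(4L, sim$truth[gene_id == g, length_nt])
  for (k in seq_len(max_k)) {
    sp <- simulate_collinear_partner(sim, data.table(gene_id = g, n_subs = k,
                                                     merge = FALSE))
    rec <- assess_conservation(mexs[gene_id == g], sp$pairs[gene_a == g],
                               sim$genes, sp$partner$genes)
    expect_equal(rec$verdict, "conserved_substituted")
    expect_equal(rec$n_substitutions, k)
  }
})

test_that("substitution request beyond micro-exon length errors", {
  sim <- sim_cons()
  g <- sim$truth$gene_id[1]
  too_many <- sim$truth[gene_id == g, length_nt] + 1L
  expect_error(simulate_collinear_partner(
    sim, data.table(gene_id = g, n_subs = too_many, merge = FALSE)),
    "exceed")
})

test_that("phase mismatch and non-coding micro-exons are handled", {
  sim <- sim_cons()
  mexs <- extract_annotated_microexons(sim$genes)
  fake <- copy(mexs[1])[, coding_status := "utr"]
  sp <- simulate_collinear_partner(sim)
  expect_error(map_microexon_to_partner(fake, sp$pairs[1], sim$genes,
                                        sp$partner$genes),
               "not coding")
  # judge on a constructed mapped record with differing phases
  mapped <- data.table(mex_id = "m", gene_a = "a", gene_b = "b", block_id = "1",
                       phase_a = 1L, len_a = 45L, aa_start_a = 1L, aa_end_a = 15L,
                       seq_a = strrep("A", 45), status = "mapped", phase_b = 2L,
                       len_b = 45L, aa_start_b = 1L, aa_end_b = 15L,
                       seq_b = strrep("A", 45), exon_merged = FALSE)
  expect_equal(judge_conservation(mapped)$verdict, "not_conserved")
  una <- copy(mapped)[, status := "unalignable"]
  expect_equal(judge_conservation(una)$verdict, "unalignable")
})

test_that("domain consistency categories mirror the four structural cases", {
  rec <- data.table(mex_id = "m", gene_a = "a", gene_b = "b",
                    status = "mapped", aa_start_a = 10L, aa_end_a = 20L,
                    aa_start_b = 10L, aa_end_b = 20L, exon_merged = FALSE)
  da <- data.table(protein_id = "a", accession = "PF00847", start = 5L, end = 30L)
  db_same <- data.table(protein_id = "b", accession = "PF00847", start = 5L, end = 30L)
  db_none <- data.table(protein_id = "b", accession = "PF99999", start = 50L, end = 60L)

  r1 <- domain_consistency(rec, da, db_same)
  expect_true(r1$domain_consistent)
  expect_equal(r1$domain_category, "same-structure-same-domain")

  r2 <- domain_consistency(rec, da, db_none)
  expect_false(r2$domain_consistent)
  expect_equal(r2$domain_category, "different-structure-one-domain")

  rec_m <- copy(rec)[, exon_merged := TRUE]
  expect_equal(domain_consistency(rec_m, da, db_same)$domain_category,
               "merged-exon-similar-domain")
  expect_equal(domain_consistency(rec_m, da, db_none)$domain_category,
               "merged-exon-different-domain")
  # missing tables -> unknown
  expect_true(is.na(domain_consistency(rec, NULL, NULL)$domain_consistent))
})

test_that("summary layout: counts, inequality, empty input", {
  recs <- data.table(
    species = "sp1",
    mex_id = c("m1", "m2", "m3", "m4", "m5", "m6"),
    gene_a = c("g1", "g1", "g2", "g3", "g4", "g4"),
    gene_b = paste0(c("g1", "g1", "g2", "g3", "g4", "g4"), "_p"),
    verdict = c("conserved_identical", "conserved_substituted",
                "conserved_identical", "not_conserved",
                "conserved_identical", "conserved_identical"),
    domain_consistent = c(TRUE, TRUE, FALSE, FALSE, NA, TRUE))
  s <- conservation_summary(recs, total_pairs = c(sp1 = 10L))
  expect_equal(s$table$gene_pairs, 10L)
  expect_equal(s$table$pairs_with_mex, 4L)
  expect_equal(s$table$pairs_with_conserved_mex, 3L)
  expect_equal(s$table$conserved_mex_count, 5L)
  expect_gte(s$table$conserved_mex_count, s$table$pairs_with_conserved_mex)
  empty <- conservation_summary(recs[0])
  expect_equal(nrow(empty$table), 0L)
})

test_that("MCScanX and InterProScan dialects parse", {
  p <- tempfile()
  writeLines(c("############### Parameters ###############",
               "## Alignment 0: score=1000 e_value=0 N=2 chr1&chr1 plus",
               "  0-  0:\tGENE1\tGENE1_p\t  0",
               "  0-  1:\tGENE2\tGENE2_p\t1e-50"), p)
  pairs <- read_collinear_pairs(p)
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs$gene_a, c("GENE1", "GENE2"))
  expect_equal(pairs$block_id, c("0", "0"))

  p2 <- tempfile()
  writeLines(c("gA\tgA_p\tblk7", "gB\tgB_p"), p2)
  pairs2 <- read_collinear_pairs(p2)
  expect_equal(pairs2$gene_b, c("gA_p", "gB_p"))
  expect_equal(pairs2$block_id[1], "blk7")

  p3 <- tempfile()
  writeLines(paste("protA", "md5", "500", "Pfam", "PF00069", "Protein kinase",
                   "120", "210", "1e-30", "T", "15-10-2018", sep = "\t"), p3)
  dom <- read_interproscan(p3)
  expect_equal(dom$accession, "PF00069")
  expect_equal(dom$start, 120L)
})
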