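test_that("junction library geometry: flanks, offsets, truncation, exclusions", {
  sim <- shared_sim()
  mexs <- extract_annotated_microexons(sim$genes)
  refs <- build_junction_library(mexs, sim$genes)
  expect_true(all(refs$up_len <= 100L & refs$down_len <= 100L))
  expect_equal(nchar(refs$inclusion_seq), refs$up_len + refs$mex_len + refs$down_len)
  expect_equal(nchar(refs$exclusion_seq), refs$up_len + refs$down_len)
  expect_equal(refs$l_off, refs$up_len)
  expect_equal(refs$r_off, refs$up_len + refs$mex_len)
  # only internal micro-exons are usable
  expect_true(all(refs$mex_id %in% mexs[positional_class == "internal", mex_id]))
  # inclusion minus the micro-exon slice equals exclusion
  joined <- paste0(substring(refs$inclusion_seq, 1, refs$up_len),
                   substring(refs$inclusion_seq, refs$r_off + 1,
                             nchar(refs$inclusion_seq)))
  expect_equal(joined, refs$exclusion_seq)
})

test_that("first/last micro-exons are excluded from the library with a reason", {
  f <- toy_annotation_files()
  genes <- load_annotation(f$gff3, f$fasta)
  mexs <- extract_annotated_microexons(genes)
  refs <- suppressMessages(build_junction_library(mexs, genes))
  expect_equal(nrow(refs), 1L)                       # the internal 12-nt one
  expect_equal(refs$mex_len, 12L)
  expect_equal(nchar(refs$inclusion_seq), 212L)      # 100 + 12 + 100
  expect_equal(nchar(refs$exclusion_seq), 200L)
})

test_that("micro-exons within 100 spliced nt share a merged group", {
  f <- toy_annotation_files()
  genes <- load_annotation(f$gff3, f$fasta)
  # add a second micro-exon 60 spliced nt downstream of [1001,1012] to GA.1:
  # inject an exon [1061,1072] between 1012 and 1301
  ex <- rbind(genes$exons,
              data.table(transcript_id = "GA.1", chrom = "chrT", strand = "+",
                         start = 1061L, end = 1072L, exon_rank = 0L))
  genes2 <- microexon:::finalize_gene_models(genes$genes, genes$transcripts, ex,
                                             genes$cds, genes$seq)
  mexs <- extract_annotated_microexons(genes2)
  refs <- suppressMessages(build_junction_library(mexs, genes2))
  grp <- refs[mex_len == 12L]
  expect_equal(nrow(grp), 2L)
  expect_equal(length(unique(grp$group_id)), 1L)
})

test_that("junction counting honours the 3-nt overhang on both sides", {
  refs <- data.table(mex_id = "m1", group_id = "g", transcript_id = "t",
                     up_len = 100L, mex_len = 12L, down_len = 100L,
                     l_off = 100L, r_off = 112L, skip_off = 100L,
                     inclusion_seq = strrep("A", 212), exclusion_seq = strrep("A", 200))
  mk <- function(rname, pos, len = 20L)
    data.table(qname = "r", flag = 0L, rname = rname, pos = pos, mapq = 60L,
               cigar = sprintf("%dM", len), seq = strrep("A", len), nm = 0L)
  # alignment [84,103] covers the L junction (after base 100) with exactly
  # 3 nt beyond it -> R_L; it stops before the R junction -> no R_R
  cnt <- count_junction_reads(list(s1 = mk("m1|incl", 84L)), refs)
  expect_equal(cnt$R_L, 1L)
  expect_equal(cnt$R_R, 0L)
  # [83,102]: only 2 nt beyond the L junction -> not counted
  cnt0 <- count_junction_reads(list(s1 = mk("m1|incl", 83L)), refs)
  expect_equal(cnt0$R_L, 0L)
  # read ending exactly 2 nt past the skip junction -> not counted
  cnt2 <- count_junction_reads(list(s1 = mk("m1|excl", 83L)), refs)
  expect_equal(cnt2$R_skipped, 0L)
  # one more base of overlap counts
  cnt3 <- count_junction_reads(list(s1 = mk("m1|excl", 84L)), refs)
  expect_equal(cnt3$R_skipped, 1L)
  # a read across a short micro-exon supports both inclusion junctions
  cnt4 <- count_junction_reads(list(s1 = mk("m1|incl", 95L, 25L)), refs)
  expect_equal(cnt4$R_L, 1L)
  expect_equal(cnt4$R_R, 1L)
  expect_equal(cnt4$R_tot, 2L)
  # unknown reference -> warning, skipped
  expect_warning(count_junction_reads(list(s1 = mk("nope|incl", 98L)), refs),
                 "unknown reference")
})

test_that("compute_psi reproduces the published arithmetic", {
  cnt <- data.table(mex_id = c("a", "b", "c"), sample_id = "s",
                    R_L = c(30L, 10L, 4L), R_R = c(20L, 10L, 3L),
                    R_skipped = c(10L, 0L, 2L))
  p <- compute_psi(cnt)
  expect_equal(p$R_tot, c(40L, 20L, 6L))
  expect_equal(p$psi, c(0.8, 1.0, NA_real_))
  expect_equal(p$splice_class, c("AS", "CS", "missing"))
})

test_that("compute_psi equals the brute-force oracle on the full 0..50 grid", {
  grid <- as.data.table(expand.grid(R_L = 0:50, R_R = 0:50, R_skipped = 0:50))
  grid[, `:=`(mex_id = sprintf("m%07d", .I), sample_id = "s")]
  got <- compute_psi(grid)
  want <- mapply(psi_oracle, grid$R_L, grid$R_R, grid$R_skipped)
  expect_equal(got$psi, unname(want))
  # invariants: psi in [0,1]; psi == 1 iff no skip support (when covered)
  ok <- !is.na(got$psi)
  expect_true(all(got$psi[ok] >= 0 & got$psi[ok] <= 1))
  expect_true(all((got$psi[ok] == 1) == (got$R_skipped[ok] == 0 & got$R_tot[ok] > 0)))
})

test_that("PSI is monotone in min(R_L, R_R) at fixed R_skipped", {
  skips <- 12L
  psis <- compute_psi(data.table(mex_id = "m", sample_id = "s",
                                 R_L = 5:40, R_R = 60L, R_skipped = skips))$psi
  expect_true(all(diff(psis) >= 0, na.rm = TRUE))
})

test_that("replicate merging: three-case rule, symmetry, strictness", {
  expect_equal(merge_replicates(0.8, NA_real_), 0.8)
  expect_equal(merge_replicates(NA_real_, 0.8), 0.8)
  expect_equal(merge_replicates(0.80, 0.85), 0.825)
  expect_true(is.na(merge_replicates(0.50, 0.70)))
  expect_true(is.na(merge_replicates(0.50, 0.60)))   # |d| == 0.10 -> missing
  expect_true(is.na(merge_replicates(NA_real_, NA_real_)))

  g <- seq(0, 1, by = 0.05)
  vals <- c(g, NA_real_)
  pairs <- expand.grid(a = vals, b = vals)
  got <- merge_replicates(pairs$a, pairs$b)
  want <- mapply(merge_oracle, pairs$a, pairs$b)
  expect_equal(got, unname(want))
  # symmetry
  expect_equal(got, merge_replicates(pairs$b, pairs$a))
})

test_that("table-interface merge checks mex ids and recomputes classes", {
  a <- data.table(mex_id = c("m1", "m2"), psi = c(0.95, NA_real_))
  b <- data.table(mex_id = c("m1", "m2"), psi = c(0.97, 0.5))
  m <- merge_replicates(a, b, unit_id = "u1")
  expect_equal(m[mex_id == "m1", psi], 0.96)
  expect_equal(m[mex_id == "m2", splice_class], "AS")
  expect_error(merge_replicates(a, data.table(mex_id = c("m1", "zz"), psi = c(1, 1))),
               "mismatched")
})

test_that("splice classification boundaries", {
  expect_equal(classify_splicing(c(0.95, 0.9, 0.89999, 0.5, 0.1, 0.05, NA)),
               c("CS", "CS", "AS", "AS", "AS", "low", "missing"))
})

test_that("tissue expression sets: membership, specificity, overlap", {
  mk <- function(mex, tissue, psis)
    data.table(mex_id = mex, tissue = tissue,
               unit_id = sprintf("%s_u%d", tissue, seq_along(psis)), psi = psis)
  long <- rbind(
    mk("mA", "panicle", c(0.4, 0.4, 0.4)),        # panicle-specific
    mk("mA", "root", c(0.05, NA)),
    mk("mB", "panicle", c(0.2, 0.2)), mk("mB", "root", c(0.2, 0.2)),
    mk("mB", "shoot", c(0.2, 0.2)), mk("mB", "leaf", c(0.2, 0.2)),
    mk("mC", "root", c(0.4, NA)))                  # only 1 qualifying unit
  sets <- tissue_expression_sets(long, tissues = c("leaf", "panicle", "root", "shoot"))
  expect_equal(sets$specific$panicle, "mA")
  expect_true("mB" %in% sets$expressed$mex_id[rowSums(
    as.matrix(sets$expressed[, -1])) == 4])
  expect_equal(sets$overlap[combination == "leaf+panicle+root+shoot", count], 1L)
  expect_false("mC" %in% unlist(sets$specific))
  expect_error(tissue_expression_sets(long, tissues = c("leaf")), "unknown tissue")
})

test_that("2-min rule caps PSI when one junction is inflated (robustness)", {
  base <- data.table(mex_id = "m", sample_id = "s", R_L = 50L, R_R = 50L,
                     R_skipped = 50L)
  inflated <- copy(base)[, R_L := 500L]
  expect_equal(compute_psi(base)$psi, compute_psi(inflated)$psi)
})
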