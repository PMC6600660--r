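test_that("load_annotation builds the hierarchy and converts coordinates", {
  f <- toy_annotation_files()
  genes <- load_annotation(f$gff3, f$fasta)
  expect_s3_class(genes, "gene_models")
  expect_equal(nrow(genes$genes), 2L)
  expect_equal(nrow(genes$transcripts), 3L)
  # GFF3 `exon 101 112` -> width 12
  e1 <- genes$exons[transcript_id == "GA.1"][1]
  expect_equal(e1$end - e1$start + 1L, 12L)
  expect_equal(genes$transcripts[gene_id == "GA", transcript_id], c("GA.1", "GA.2"))
})

test_that("malformed parentage and missing chromosomes raise named errors", {
  f <- toy_annotation_files()
  bad <- readLines(f$gff3)
  bad <- c(bad, "chrT\ttoy\texon\t2900\t2950\t.\t+\t.\tParent=GHOST.1")
  bad_path <- tempfile(fileext = ".gff3")
  writeLines(bad, bad_path)
  expect_error(load_annotation(bad_path, f$fasta), "GHOST\\.1")

  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">otherchr", "ACGT"), fa2)
  expect_error(load_annotation(f$gff3, fa2), "chrT")
})

test_that("extraction applies length bounds, classes and frame rule", {
  f <- toy_annotation_files()
  genes <- load_annotation(f$gff3, f$fasta)
  mexs <- extract_annotated_microexons(genes)
  expect_setequal(mexs$length_nt, c(12L, 12L, 46L))

  m_utr <- mexs[start == 101]
  expect_equal(m_utr$positional_class, "first")
  expect_equal(m_utr$coding_status, "utr")

  # internal in GA.1, last in GA.2 -> internal; fully CDS; shared -> one record
  m_int <- mexs[start == 1001]
  expect_equal(nrow(m_int), 1L)
  expect_equal(m_int$positional_class, "internal")
  expect_equal(m_int$coding_status, "cds")
  expect_equal(m_int$frame_class, "in_frame")
  expect_equal(m_int$transcript_ids, "GA.1,GA.2")

  # 46 nt on the minus strand: first exon in transcription order, frame-shifting
  m_46 <- mexs[length_nt == 46]
  expect_equal(m_46$positional_class, "first")
  expect_equal(m_46$frame_class, "frame_shifting")
  expect_equal(m_46$gene_id, "GB")
  # minus-strand sequence is reverse-complemented
  plus <- substr(f$chr_seq, 2601, 2646)
  expect_equal(m_46$sequence,
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus))))
})

test_that("length bounds are inclusive at 3 and 51 and exclusive beyond", {
  sim <- shared_sim()
  ex <- data.table::copy(sim$genes$exons)
  # synthetic check on bound arithmetic through a constructed gene set
  g <- sim$genes
  mexs49 <- extract_annotated_microexons(g, min_len = 3L, max_len = 51L)
  expect_true(all(mexs49$length_nt >= 3L & mexs49$length_nt <= 51L))
  # type invariants on every record
  expect_true(all(mexs49$length_nt == mexs49$end - mexs49$start + 1L))
  expect_true(all(mexs49$length_nt == nchar(mexs49$sequence)))
  expect_true(all((mexs49$length_nt %% 3L == 0L) == (mexs49$frame_class == "in_frame")))
  # widening the window by one admits 52-nt exons, narrowing drops 51s
  w52 <- extract_annotated_microexons(g, 3L, 52L)
  expect_true(all(w52$length_nt <= 52L))
  expect_gte(nrow(w52), nrow(mexs49))
})

test_that("extraction matches a brute-force scan of the raw GFF3 (oracle)", {
  sim <- shared_sim()
  d <- tempfile()
  paths <- write_sim(sim, d)
  genes <- load_annotation(paths[["gff3"]], paths[["fasta"]])
  mexs <- extract_annotated_microexons(genes)

  raw <- data.table::fread(paths[["gff3"]], skip = 1, header = FALSE)
  exon_rows <- raw[V3 == "exon"]
  exon_rows[, len := V5 - V4 + 1L]
  brute <- unique(exon_rows[len >= 3 & len <= 51, .(chrom = V1, start = V4, end = V5)])
  data.table::setorder(brute, chrom, start, end)
  got <- unique(mexs[, .(chrom, start, end)])
  data.table::setorder(got, chrom, start, end)
  expect_equal(as.data.frame(got), as.data.frame(brute))
})

test_that("extraction is deterministic and BED round-trips", {
  sim <- shared_sim()
  a <- extract_annotated_microexons(sim$genes)
  b <- extract_annotated_microexons(sim$genes)
  expect_identical(a, b)

  bed <- tempfile(fileext = ".bed")
  write_microexon_bed(a, bed)
  back <- read_microexon_bed(bed)
  expect_equal(back[, .(chrom, start, end)], a[, .(chrom, start, end)])
  expect_equal(back$score, a$length_nt)
})

test_that("length distribution summary counts and in-frame fraction", {
  mexs <- data.table::data.table(
    mex_id = sprintf("m%d", 1:4), chrom = "c", start = 1:4, end = 1:4,
    strand = "+", length_nt = c(9L, 12L, 45L, 46L), gene_id = "g",
    transcript_ids = "t", positional_class = c("internal", "internal", "first", "last"),
    coding_status = "cds",
    frame_class = c("in_frame", "in_frame", "in_frame", "frame_shifting"),
    sequence = "NNN")
  s <- summarize_length_distribution(mexs)
  expect_equal(s$in_frame_fraction, 0.75)
  expect_equal(s$table[positional_class == "internal", sum(count)], 2L)
  empty <- summarize_length_distribution(mexs[0])
  expect_equal(nrow(empty$table), 0L)
})
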