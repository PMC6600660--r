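#' Load gene models from a GFF3 annotation and genome FASTA
#'
#' Parses a GFF3 file with the standard gene/mRNA/exon/CDS hierarchy together
#' with the genome sequence and returns a validated `gene_models` object. All
#' coordinates are stored 1-based inclusive (the GFF3/Bioconductor convention);
#' BED output converts to 0-based half-open at the I/O boundary.
#'
#' @param gff3_path Path to a GFF3 annotation file.
#' @param fasta_path Path to the genome FASTA. Sequence names must cover every
#'   chromosome referenced by the annotation.
#' @return An object of class `gene_models`: a list with data.tables `genes`
#'   (gene_id, chrom, strand, start, end), `transcripts`, `exons` (sorted by
#'   genomic start within transcript, `exon_rank` in genomic order), `cds`
#'   (with `phase`), and the genome as a [Biostrings::DNAStringSet] in `$seq`.
#' @details Malformed parentage (an mRNA whose Parent gene or an exon/CDS whose
#'   Parent mRNA is absent) raises an error naming the offending feature, as
#'   does a chromosome missing from the FASTA.
#' @export
load_annotation <- function(gff3_path, fasta_path) {
  if (!file.exists(gff3_path)) stop_mex("GFF3 file not found: %s", gff3_path)
  if (!file.exists(fasta_path)) stop_mex("FASTA file not found: %s", fasta_path)
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  seq <- Biostrings::readDNAStringSet(fasta_path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  build_gene_models(gff, seq)
}

# Assemble and validate the gene/transcript/exon/CDS hierarchy from an
# imported GFF3 GRanges. Split out so the simulator can reuse it.
build_gene_models <- function(gff, seq) {
  md <- as.data.table(GenomicRanges::mcols(gff)[, intersect(
    c("type", "ID", "Parent", "phase"), names(GenomicRanges::mcols(gff))), drop = FALSE])
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end   = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    type = as.character(md$type),
    ID = if ("ID" %in% names(md)) as.character(md$ID) else NA_character_,
    parent = if ("Parent" %in% names(md))
      vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_, "")
    else NA_character_,
    phase = if ("phase" %in% names(md)) as.integer(md$phase) else NA_integer_
  )

  genes <- dt[type == "gene", .(gene_id = ID, chrom, strand, start, end)]
  tx_types <- c("mRNA", "transcript")
  txs <- dt[type %in% tx_types,
            .(transcript_id = ID, gene_id = parent, chrom, strand, start, end)]
  bad_tx <- txs[!gene_id %in% genes$gene_id]
  if (nrow(bad_tx))
    stop_mex("GFF3 parentage error: transcript '%s' references missing gene '%s'",
             bad_tx$transcript_id[1], bad_tx$gene_id[1])

  exons <- dt[type == "exon", .(transcript_id = parent, chrom, strand, start, end)]
  cds <- dt[type == "CDS", .(transcript_id = parent, chrom, strand, start, end, phase)]
  bad_ex <- exons[!transcript_id %in% txs$transcript_id]
  if (nrow(bad_ex))
    stop_mex("GFF3 parentage error: exon at %s:%d-%d references missing mRNA '%s'",
             bad_ex$chrom[1], bad_ex$start[1], bad_ex$end[1], bad_ex$transcript_id[1])
  bad_cds <- cds[!transcript_id %in% txs$transcript_id]
  if (nrow(bad_cds))
    stop_mex("GFF3 parentage error: CDS at %s:%d-%d references missing mRNA '%s'",
             bad_cds$chrom[1], bad_cds$start[1], bad_cds$end[1], bad_cds$transcript_id[1])

  if (!is.null(seq)) {
    missing_chr <- setdiff(unique(genes$chrom), names(seq))
    if (length(missing_chr))
      stop_mex("chromosome '%s' referenced by annotation is absent from FASTA", missing_chr[1])
  }

  finalize_gene_models(genes, txs, exons, cds, seq)
}

# sort, rank and validate the component tables of a gene_models object
finalize_gene_models <- function(genes, txs, exons, cds, seq) {
  genes <- as.data.table(genes); txs <- as.data.table(txs)
  exons <- as.data.table(exons); cds <- as.data.table(cds)
  setorder(exons, transcript_id, start)
  exons[, exon_rank := seq_len(.N), by = transcript_id]
  setorder(cds, transcript_id, start)
  setorder(genes, chrom, start, gene_id)
  setorder(txs, chrom, start, transcript_id)

  # strand consistency + exon disjointness
  chk <- merge(txs[, .(transcript_id, tx_strand = strand)],
               exons[, .(transcript_id, strand)], by = "transcript_id")
  if (nrow(chk[strand != tx_strand]))
    stop_mex("strand conflict within transcript '%s'", chk[strand != tx_strand]$transcript_id[1])
  ovl <- exons[, .(bad = any(start[-1] <= end[-.N] & .N > 1)), by = transcript_id][bad == TRUE]
  if (nrow(ovl)) stop_mex("overlapping exons in transcript '%s'", ovl$transcript_id[1])

  structure(list(genes = genes, transcripts = txs, exons = exons, cds = cds, seq = seq),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts, %d exons, %d CDS segments, %s\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$cds),
              if (is.null(x$seq)) "no genome sequence"
              else sprintf("%d sequence(s)", length(x$seq))))
  invisible(x)
}

# spliced (mature) sequence of one transcript, in transcription orientation
transcript_spliced_seq <- function(genes, transcript_id) {
  idx <- which(genes$exons$transcript_id == transcript_id)
  ex <- genes$exons[idx]
  setorder(ex, start)
  parts <- vapply(seq_len(nrow(ex)), function(i)
    as.character(Biostrings::subseq(genes$seq[[ex$chrom[i]]], ex$start[i], ex$end[i])), "")
  s <- paste(parts, collapse = "")
  if (ex$strand[1] == "-") s <- reverse_complement(s)
  s
}

#' Extract micro-exons from annotation
#'
#' Scans every transcript's exons and returns one record per distinct genomic
#' interval with length between `min_len` and `max_len` nucleotides.
#'
#' @param genes A `gene_models` object from [load_annotation()].
#' @param min_len,max_len Inclusive micro-exon length bounds in nt (defaults
#'   3 and 51).
#' @return A data.table with one row per micro-exon: `mex_id`, `chrom`,
#'   `start`, `end`, `strand`, `length_nt`, `gene_id`, `transcript_ids`
#'   (comma-separated), `positional_class` (first/internal/last/single),
#'   `coding_status` (cds/utr/mixed), `frame_class`
#'   (in_frame/frame_shifting), and `sequence` (reverse-complemented on the
#'   minus strand).
#' @details The micro-exon length is the exon length; the CDS relationship is
#'   reported separately in `coding_status` (cds when the CDS of transcripts
#'   carrying the exon covers the whole interval, utr when it covers none of
#'   it, mixed otherwise). An interval shared by several transcripts is one
#'   record; a positional-class conflict resolves to `internal` whenever any
#'   transcript places the exon internally, otherwise by majority.
#' @export
extract_annotated_microexons <- function(genes, min_len = 3L, max_len = 51L) {
  stopifnot(inherits(genes, "gene_models"))
  if (min_len < 1 || max_len < min_len) stop_mex("invalid length bounds [%s,%s]", min_len, max_len)
  ex <- copy(genes$exons)
  if (!nrow(ex)) return(empty_microexon_table())
  ex[, exon_len := end - start + 1L]
  ex[, n_exons := .N, by = transcript_id]
  # positional class in transcription order
  ex[, positional_class := "internal"]
  ex[n_exons == 1L, positional_class := "single"]
  ex[n_exons > 1L & strand == "+" & exon_rank == 1L, positional_class := "first"]
  ex[n_exons > 1L & strand == "+" & exon_rank == n_exons, positional_class := "last"]
  ex[n_exons > 1L & strand == "-" & exon_rank == n_exons, positional_class := "first"]
  ex[n_exons > 1L & strand == "-" & exon_rank == 1L, positional_class := "last"]

  mex <- ex[exon_len >= min_len & exon_len <= max_len]
  if (!nrow(mex)) return(empty_microexon_table())
  mex <- merge(mex, genes$transcripts[, .(transcript_id, gene_id)], by = "transcript_id")

  resolve_class <- function(cls) {
    if (any(cls == "internal")) return("internal")
    tab <- sort(table(cls), decreasing = TRUE)
    if (sum(tab == tab[1]) > 1L) "internal" else names(tab)[1]
  }
  out <- mex[, .(
    length_nt = exon_len[1],
    transcript_ids = paste(sort(unique(transcript_id)), collapse = ","),
    positional_class = resolve_class(positional_class)
  ), by = .(gene_id, chrom, start, end, strand)]

  out[, coding_status := mapply(coding_status_of, chrom, start, end,
                                strsplit(transcript_ids, ","),
                                MoreArgs = list(genes = genes))]
  out[, frame_class := ifelse(length_nt %% 3L == 0L, "in_frame", "frame_shifting")]
  if (!is.null(genes$seq)) {
    out[, sequence := {
      s <- vapply(seq_len(.N), function(i)
        as.character(Biostrings::subseq(genes$seq[[chrom[i]]], start[i], end[i])), "")
      ifelse(strand == "-", reverse_complement(s), s)
    }]
  } else out[, sequence := NA_character_]
  setorder(out, chrom, start, end, gene_id)
  out[, mex_id := sprintf("%s:%s:%d-%d", gene_id, chrom, start, end)]
  data.table::setcolorder(out, c("mex_id", "chrom", "start", "end", "strand", "length_nt",
                                 "gene_id", "transcript_ids", "positional_class",
                                 "coding_status", "frame_class", "sequence"))
  out[]
}

empty_microexon_table <- function() {
  data.table(mex_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), length_nt = integer(),
             gene_id = character(), transcript_ids = character(),
             positional_class = character(), coding_status = character(),
             frame_class = character(), sequence = character())
}

# cds / utr / mixed for an interval, judged over the transcripts that carry it
coding_status_of <- function(chrom, start, end, transcript_ids, genes) {
  sel <- genes$cds$transcript_id %in% transcript_ids &
    genes$cds$chrom == chrom &
    genes$cds$end >= start & genes$cds$start <= end
  idx <- which(sel)
  cds <- genes$cds[idx]
  if (!nrow(cds)) return("utr")
  cov <- IRanges::reduce(IRanges::IRanges(pmax(cds$start, start), pmin(cds$end, end)))
  covered <- sum(IRanges::width(cov))
  if (covered >= end - start + 1L) "cds" else "mixed"
}

#' Summarize the micro-exon length distribution
#'
#' @param mexs Micro-exon table from [extract_annotated_microexons()].
#' @return A list with `table` — counts by (positional_class, length_nt) — and
#'   `in_frame_fraction`, the fraction of micro-exons whose length is a
#'   multiple of three.
#' @export
summarize_length_distribution <- function(mexs) {
  if (!nrow(mexs))
    return(list(table = data.table(positional_class = character(),
                                   length_nt = integer(), count = integer()),
                in_frame_fraction = NA_real_))
  tab <- mexs[, .(count = .N), by = .(positional_class, length_nt)]
  setorder(tab, positional_class, length_nt)
  list(table = tab[], in_frame_fraction = mean(mexs$length_nt %% 3L == 0L))
}

#' Write micro-exons as BED6
#'
#' Coordinates convert to BED's 0-based half-open convention; the name column
#' is the micro-exon id and the score is the length in nt.
#' @param mexs Micro-exon table.
#' @param path Output path.
#' @export
write_microexon_bed <- function(mexs, path) {
  bed <- mexs[, .(chrom, start = start - 1L, end, name = mex_id,
                  score = length_nt, strand)]
  fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6 file of micro-exon intervals back into 1-based coordinates
#' @param path BED6 file written by [write_microexon_bed()].
#' @export
read_microexon_bed <- function(path) {
  bed <- fread(path, header = FALSE,
               col.names = c("chrom", "start", "end", "mex_id", "score", "strand"))
  bed[, start := start + 1L]
  bed[]
}

#' Write the full micro-exon table as TSV
#' @param mexs Micro-exon table.
#' @param path Output path.
#' @export
write_microexon_tsv <- function(mexs, path) {
  fwrite(mexs, path, sep = "\t", quote = FALSE)
  invisible(path)
}
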