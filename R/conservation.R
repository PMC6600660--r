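# Conservation of micro-exons across collinear gene pairs: a micro-exon is
# conserved when its homologous span in the partner gene has the same CDS
# phase and the same CDS length; nucleotide substitutions are then counted on
# the back-mapped coding sequence.

# transcript with the longest total CDS for a gene
longest_cds_transcript <- function(genes, gene_id) {
  idx <- which(genes$transcripts$gene_id == gene_id)
  txs <- genes$transcripts$transcript_id[idx]
  if (!length(txs)) stop_mex("gene '%s' not found in annotation", gene_id)
  cl <- genes$cds[transcript_id %in% txs,
                  .(cds_len = sum(end - start + 1L)), by = transcript_id]
  if (!nrow(cl)) stop_mex("gene '%s' has no CDS", gene_id)
  setorder(cl, -cds_len, transcript_id)
  cl$transcript_id[1]
}

# CDS segments of a transcript in transcription order with CDS-spliced
# coordinates (sp_start/sp_end, 1-based nt within the spliced CDS) and the
# full spliced CDS sequence in transcription orientation.
cds_spliced_info <- function(genes, transcript_id) {
  idx <- which(genes$cds$transcript_id == transcript_id)
  cds <- genes$cds[idx]
  if (!nrow(cds)) stop_mex("transcript '%s' has no CDS", transcript_id)
  setorder(cds, start)
  parts <- vapply(seq_len(nrow(cds)), function(i)
    as.character(Biostrings::subseq(genes$seq[[cds$chrom[i]]], cds$start[i], cds$end[i])), "")
  s <- paste(parts, collapse = "")
  if (cds$strand[1] == "-") {
    # revcomp of the genomic concatenation reverses segment order, matching
    # the row reversal into transcription order
    s <- reverse_complement(s)
    cds <- cds[rev(seq_len(nrow(cds)))]
  }
  w <- cds$end - cds$start + 1L
  cds[, `:=`(sp_end = cumsum(w), sp_start = cumsum(w) - w + 1L)]
  list(segments = cds[], seq = s)
}

protein_of <- function(genes, gene_id) {
  tx <- longest_cds_transcript(genes, gene_id)
  info <- cds_spliced_info(genes, tx)
  n <- nchar(info$seq)
  usable <- info$seq
  if (n %% 3L != 0L) usable <- substring(usable, 1L, n - n %% 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(usable),
                                           if.fuzzy.codon = "solve"))
  aa <- sub("\\*$", "", aa)
  list(transcript_id = tx, info = info, protein = aa)
}

#' Globally align two protein sequences (BLOSUM62, affine gaps)
#'
#' Bundled so conservation fixtures are self-contained; externally computed
#' alignments (aligned FASTA) can be supplied instead wherever an alignment
#' argument is accepted.
#' @param a,b Protein sequences (plain strings).
#' @param gap_open,gap_extend Affine gap penalties (defaults 11 and 1).
#' @return list with `pattern` and `subject`: the two aligned strings
#'   (equal length, "-" for gaps).
#' @export
align_proteins <- function(a, b, gap_open = 11, gap_extend = 1) {
  BL <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = BL, gapOpening = gap_open, gapExtension = gap_extend)
  list(pattern = as.character(Biostrings::alignedPattern(pa)),
       subject = as.character(Biostrings::alignedSubject(pa)))
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Read an aligned-FASTA pairwise alignment
#' @param path FASTA with exactly two aligned (gapped) sequences.
#' @return list(pattern=, subject=) of the two aligned strings.
#' @export
read_pairwise_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) != 2L) stop_mex("expected 2 aligned sequences in %s, got %d", path, length(ss))
  list(pattern = as.character(ss[[1]]), subject = as.character(ss[[2]]))
}

#' Read MCScanX-style collinearity output into gene pairs
#'
#' Accepts the MCScanX `.collinearity` dialect (`## Alignment n:` block
#' headers, pair lines with two gene ids) or any 2/3-column TSV of
#' gene_a/gene_b(/block_id).
#' @param path Collinearity file.
#' @return data.table `gene_a`, `gene_b`, `block_id`.
#' @export
read_collinear_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  block <- "0"
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("Alignment\\s+(\\S+?):", ln))[[1]]
      if (length(m) == 2L) block <- m[2]
      next
    }
    f <- strsplit(sub("^\\s+", "", ln), "[\t ]+")[[1]]
    f <- f[nzchar(f)]
    # MCScanX pair lines look like "0-  0:  geneA  geneB  0"; plain TSV is geneA geneB [block]
    if (grepl(":$", f[1]) || grepl("^\\d+-$", f[1])) f <- f[-seq_len(which(grepl(":$", f))[1])]
    if (length(f) >= 2L)
      out[[i]] <- data.table(gene_a = f[1], gene_b = f[2],
                             block_id = if (length(f) >= 3L && !grepl("^[0-9.eE+-]+$", f[3]))
                               f[3] else block)
  }
  res <- rbindlist(out)
  if (!nrow(res)) stop_mex("no gene pairs parsed from %s", path)
  res[]
}

#' Read an InterProScan-style TSV domain table
#'
#' Uses columns 1 (protein/gene id), 5 (signature accession), 7 and 8
#' (amino-acid start/stop) of the standard InterProScan TSV layout.
#' @param path TSV path.
#' @return data.table `protein_id`, `accession`, `start`, `end` (aa).
#' @export
read_interproscan <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 8L) stop_mex("domain table %s has %d columns; >= 8 expected", path, ncol(dt))
  out <- dt[, .(protein_id = as.character(V1), accession = as.character(V5),
                start = as.integer(V7), end = as.integer(V8))]
  out[]
}

# amino-acid index maps between the two rows of a gapped alignment
alignment_maps <- function(alignment) {
  pa <- strsplit(alignment$pattern, "")[[1]]
  sb <- strsplit(alignment$subject, "")[[1]]
  if (length(pa) != length(sb)) stop_mex("alignment rows differ in length")
  data.table(col = seq_along(pa),
             a_pos = cumsum(pa != "-") * (pa != "-"),
             b_pos = cumsum(sb != "-") * (sb != "-"))
}

#' Locate a micro-exon's homologous span in a collinear partner gene
#'
#' The micro-exon's amino-acid span in its own protein is read off the
#' pairwise protein alignment; aligned partner positions are mapped back to
#' the partner transcript's CDS exon structure, returning the partner exon's
#' CDS length and phase at that span.
#'
#' @param mex One-row micro-exon record (must be coding: conservation is
#'   defined on CDS).
#' @param pair One-row collinear pair (`gene_a`, `gene_b`, `block_id`); the
#'   micro-exon must belong to `gene_a`.
#' @param genes_a,genes_b `gene_models` for the two species (with sequence).
#' @param alignment Optional precomputed alignment
#'   (list(pattern=, subject=)); when NULL the bundled aligner is used.
#' @return A one-row data.table "mapped record" with phases, lengths, spans,
#'   the two nucleotide sequences over the span, and a `status` of
#'   "mapped" or "unalignable"; feed to [judge_conservation()].
#' @export
map_microexon_to_partner <- function(mex, pair, genes_a, genes_b, alignment = NULL) {
  mex <- as.data.table(mex)
  if (nrow(mex) != 1L) stop_mex("map_microexon_to_partner expects a single micro-exon record")
  if (!mex$coding_status %in% "cds")
    stop_mex("micro-exon '%s' is not coding (status '%s'); conservation is defined on CDS",
             mex$mex_id, mex$coding_status)

  pa <- protein_of(genes_a, pair$gene_a)
  pb <- protein_of(genes_b, pair$gene_b)
  seg_a <- pa$info$segments
  # the micro-exon's CDS segment in the chosen transcript
  hit <- seg_a[transcript_id == pa$transcript_id & chrom == mex$chrom &
               start >= mex$start & end <= mex$end]
  if (!nrow(hit))
    stop_mex("micro-exon '%s' has no CDS segment in transcript '%s'",
             mex$mex_id, pa$transcript_id)
  phase_a <- hit$phase[1]
  len_a <- hit$end[1] - hit$start[1] + 1L
  p1 <- hit$sp_start[1]; p2 <- hit$sp_end[1]
  aa1 <- (p1 - 1L) %/% 3L + 1L; aa2 <- (p2 - 1L) %/% 3L + 1L
  aa2 <- min(aa2, nchar(pa$protein))

  if (is.null(alignment)) alignment <- align_proteins(pa$protein, pb$protein)
  maps <- alignment_maps(alignment)
  cols <- maps[a_pos >= aa1 & a_pos <= aa2 & a_pos > 0L]
  b_positions <- cols[b_pos > 0L]$b_pos
  base <- data.table(
    mex_id = mex$mex_id, gene_a = pair$gene_a, gene_b = pair$gene_b,
    block_id = pair$block_id %||% NA_character_,
    phase_a = phase_a, len_a = len_a, aa_start_a = aa1, aa_end_a = aa2,
    seq_a = substring(pa$info$seq, p1, p2))
  if (!length(b_positions)) {
    base[, `:=`(status = "unalignable", phase_b = NA_integer_, len_b = NA_integer_,
                aa_start_b = NA_integer_, aa_end_b = NA_integer_,
                seq_b = NA_character_, exon_merged = FALSE)]
    return(base[])
  }
  b1 <- min(b_positions); b2 <- max(b_positions)
  nt1 <- 3L * (b1 - 1L) + 1L; nt2 <- 3L * b2
  seg_b <- pb$info$segments
  ov <- seg_b[sp_end >= nt1 & sp_start <= nt2]
  if (!nrow(ov)) {
    base[, `:=`(status = "unalignable", phase_b = NA_integer_, len_b = NA_integer_,
                aa_start_b = b1, aa_end_b = b2, seq_b = NA_character_, exon_merged = FALSE)]
    return(base[])
  }
  ov[, overlap := pmin(sp_end, nt2) - pmax(sp_start, nt1) + 1L]
  setorder(ov, -overlap, sp_start)
  seg <- ov[1]
  len_b <- seg$sp_end - seg$sp_start + 1L
  # partner sequence over the partner exon when lengths agree (substitution
  # counting), else over the mapped span
  seq_b <- if (len_b == len_a) substring(pb$info$seq, seg$sp_start, seg$sp_end)
           else substring(pb$info$seq, max(nt1, 1L), min(nt2, nchar(pb$info$seq)))
  # codon-boundary rounding can spill the nt span <= 2 nt into a neighbour
  merged <- len_b > len_a && seg$sp_start <= nt1 + 2L && seg$sp_end >= nt2 - 2L
  base[, `:=`(status = "mapped", phase_b = seg$phase, len_b = len_b,
              aa_start_b = b1, aa_end_b = b2, seq_b = seq_b, exon_merged = merged)]
  base[]
}

#' Judge conservation of a mapped micro-exon record
#'
#' Conserved requires equal CDS phase and equal CDS length in both genes;
#' substitutions are the nucleotide Hamming distance over the span.
#' @param mapped One-row mapped record from [map_microexon_to_partner()].
#' @return The record plus `verdict` (conserved_identical /
#'   conserved_substituted / not_conserved / unalignable) and
#'   `n_substitutions` (NA unless conserved).
#' @export
judge_conservation <- function(mapped) {
  rec <- as.data.table(copy(mapped))
  if (rec$status == "unalignable") {
    rec[, `:=`(verdict = "unalignable", n_substitutions = NA_integer_)]
    return(rec[])
  }
  conserved <- !is.na(rec$phase_b) & rec$phase_a == rec$phase_b & rec$len_a == rec$len_b
  if (conserved) {
    a <- strsplit(rec$seq_a, "")[[1]]
    b <- strsplit(rec$seq_b, "")[[1]]
    nsub <- sum(a != b)
    rec[, `:=`(verdict = if (nsub == 0L) "conserved_identical" else "conserved_substituted",
               n_substitutions = as.integer(nsub))]
  } else {
    rec[, `:=`(verdict = "not_conserved", n_substitutions = NA_integer_)]
  }
  rec[]
}

#' Domain consistency of a judged micro-exon record
#'
#' Consistent means the partner protein carries the same domain accession
#' overlapping the mapped span as the reference protein does over the
#' micro-exon span.
#' @param record Judged record ([judge_conservation()]).
#' @param domains_a,domains_b Domain tables ([read_interproscan()]); NULL
#'   gives `domain_consistent = NA` (unknown).
#' @return Record plus `domain_consistent` (logical, NA = unknown) and
#'   `domain_category` over {same-structure-same-domain,
#'   different-structure-one-domain, merged-exon-similar-domain,
#'   merged-exon-different-domain, no-domain, unknown}.
#' @export
domain_consistency <- function(record, domains_a = NULL, domains_b = NULL) {
  rec <- as.data.table(copy(record))
  if (is.null(domains_a) || is.null(domains_b) || rec$status == "unalignable") {
    rec[, `:=`(domain_consistent = NA,
               domain_category = if (rec$status == "unalignable") "unknown" else "unknown")]
    return(rec[])
  }
  da <- as.data.table(domains_a)[protein_id == rec$gene_a &
                                 end >= rec$aa_start_a & start <= rec$aa_end_a]
  db <- as.data.table(domains_b)[protein_id == rec$gene_b &
                                 end >= rec$aa_start_b & start <= rec$aa_end_b]
  acc_a <- unique(da$accession); acc_b <- unique(db$accession)
  if (!length(acc_a) && !length(acc_b)) {
    rec[, `:=`(domain_consistent = NA, domain_category = "no-domain")]
    return(rec[])
  }
  consistent <- length(intersect(acc_a, acc_b)) > 0L
  category <- if (isTRUE(rec$exon_merged)) {
    if (consistent) "merged-exon-similar-domain" else "merged-exon-different-domain"
  } else if (consistent) "same-structure-same-domain" else "different-structure-one-domain"
  rec[, `:=`(domain_consistent = consistent, domain_category = category)]
  rec[]
}

#' Assess micro-exon conservation over a collinear pair table
#'
#' Convenience driver: for every pair whose `gene_a` carries coding
#' micro-exons, maps each micro-exon to the partner, judges conservation and
#' (when domain tables are given) domain consistency.
#'
#' @param mexs Micro-exon table of the reference species.
#' @param pairs Collinear pairs ([read_collinear_pairs()]).
#' @param genes_a,genes_b `gene_models` of reference and partner species.
#' @param species Partner species label recorded on each record.
#' @param domains_a,domains_b Optional domain tables.
#' @param alignments Optional named list of precomputed alignments keyed
#'   `"<gene_a>|<gene_b>"`.
#' @return data.table of ConservationRecord rows.
#' @export
assess_conservation <- function(mexs, pairs, genes_a, genes_b, species = "partner",
                                domains_a = NULL, domains_b = NULL, alignments = NULL) {
  pairs <- as.data.table(pairs)
  recs <- vector("list", 0L)
  for (i in seq_len(nrow(pairs))) {
    pm <- mexs[gene_id == pairs$gene_a[i] & coding_status == "cds"]
    if (!nrow(pm)) next
    key <- paste0(pairs$gene_a[i], "|", pairs$gene_b[i])
    alignment <- if (!is.null(alignments)) alignments[[key]] else NULL
    for (j in seq_len(nrow(pm))) {
      mapped <- map_microexon_to_partner(pm[j], pairs[i], genes_a, genes_b, alignment)
      rec <- judge_conservation(mapped)
      rec <- domain_consistency(rec, domains_a, domains_b)
      recs[[length(recs) + 1L]] <- rec
    }
  }
  out <- rbindlist(recs)
  if (!nrow(out)) return(out)
  out[, species := species]
  out[]
}

#' Per-species conservation summary (collinearity table layout)
#'
#' @param records ConservationRecord table from [assess_conservation()]
#'   (possibly several species row-bound).
#' @param total_pairs Named integer vector: total collinear gene pairs per
#'   species (a record table only sees pairs that carry micro-exons).
#' @return list with `table` — per species: `gene_pairs`, `pairs_with_mex`,
#'   `pairs_with_conserved_mex`, `conserved_mex_count` (distinct micro-exons
#'   conserved in >= 1 pair) — and `domain_consistency`: percent
#'   domain-consistent records among conserved vs non-conserved micro-exons.
#' @export
conservation_summary <- function(records, total_pairs = NULL) {
  if (!nrow(records)) {
    return(list(table = data.table(species = character(), gene_pairs = integer(),
                                   pairs_with_mex = integer(),
                                   pairs_with_conserved_mex = integer(),
                                   conserved_mex_count = integer()),
                domain_consistency = data.table(species = character(),
                                                conserved = logical(),
                                                pct_consistent = numeric())))
  }
  records <- as.data.table(records)
  records[, conserved := verdict %in% c("conserved_identical", "conserved_substituted")]
  tab <- records[, .(
    gene_pairs = if (!is.null(total_pairs)) as.integer(total_pairs[species][1])
                 else data.table::uniqueN(paste(gene_a, gene_b)),
    pairs_with_mex = data.table::uniqueN(paste(gene_a, gene_b)),
    pairs_with_conserved_mex = data.table::uniqueN(paste(gene_a, gene_b)[conserved]),
    conserved_mex_count = data.table::uniqueN(mex_id[conserved])
  ), by = species]
  dc <- records[!is.na(domain_consistent),
                .(pct_consistent = 100 * mean(domain_consistent), n = .N),
                by = .(species, conserved)]
  list(table = tab[], domain_consistency = dc[])
}
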