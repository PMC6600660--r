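#' Scan spliced alignments for internal micro-exon observations
#'
#' Every alignment with at least three reference blocks (two introns) is
#' inspected: each middle block whose length lies in `[min_len, max_len]` and
#' whose two adjacent blocks are both at least `min_anchor` nt long yields one
#' observation. Non-primary/supplementary/unmapped records, records below the
#' mapping-quality floor, and records with `>= max_mismatches` mismatches
#' (NM tag) are discarded.
#'
#' @param sam_paths Character vector of SAM paths; names are used as sample
#'   ids (unnamed paths fall back to the file base name).
#' @param min_len,max_len Candidate length bounds in nt (defaults 3, 51).
#' @param min_anchor Minimum aligned length of both flanking blocks (default
#'   6 nt).
#' @param max_mismatches Records with NM >= this are discarded (default 2,
#'   i.e. at most one mismatch survives). A missing NM tag is treated as 0
#'   and tallied.
#' @param min_mapq Mapping-quality floor used as the uniqueness proxy
#'   (default 1).
#' @return data.table of observations aggregated by (chrom, start, end,
#'   sample_id) with `n_reads` and `anchor_min` (smallest flanking anchor seen
#'   among supporting reads). Attribute `rejects` tallies discarded records.
#' @export
scan_alignments <- function(sam_paths, min_len = 3L, max_len = 51L,
                            min_anchor = 6L, max_mismatches = 2L, min_mapq = 1L) {
  sam_paths <- normalize_alignment_inputs(sam_paths)
  rejects <- c(unparseable = 0L, filtered = 0L, missing_nm = 0L)
  obs_all <- vector("list", length(sam_paths))
  for (k in seq_along(sam_paths)) {
    aln <- copy(sam_paths[[k]])
    rejects[["unparseable"]] <- rejects[["unparseable"]] + (attr(aln, "n_rejected") %||% 0L)
    if (!nrow(aln)) next
    n_missing_nm <- sum(is.na(aln$nm))
    if (n_missing_nm) {
      rejects[["missing_nm"]] <- rejects[["missing_nm"]] + n_missing_nm
      message(sprintf("%s: %d record(s) without NM tag treated as 0 mismatches",
                      names(sam_paths)[k], n_missing_nm))
      aln[is.na(nm), nm := 0L]
    }
    keep <- is_primary_alignment(aln$flag) & aln$mapq >= min_mapq & aln$nm < max_mismatches
    rejects[["filtered"]] <- rejects[["filtered"]] + sum(!keep)
    aln <- aln[keep]
    if (!nrow(aln)) next
    # only multi-gap alignments can hold a middle block
    aln <- aln[grepl("N.*N", cigar)]
    if (!nrow(aln)) next
    blocks <- cigar_ref_blocks(aln$cigar, aln$pos)
    obs <- rbindlist(Map(function(b, chrom) {
      nb <- nrow(b)
      if (nb < 3L) return(NULL)
      mid <- 2:(nb - 1L)
      w <- b[, "end"] - b[, "start"] + 1L
      left_anchor <- w[mid - 1L]
      right_anchor <- w[mid + 1L]
      ok <- w[mid] >= min_len & w[mid] <= max_len &
        left_anchor >= min_anchor & right_anchor >= min_anchor
      if (!any(ok)) return(NULL)
      data.table(chrom = chrom, start = b[mid, "start"][ok], end = b[mid, "end"][ok],
                 anchor = pmin(left_anchor, right_anchor)[ok])
    }, blocks, aln$rname))
    if (is.null(obs) || !nrow(obs)) next
    obs[, sample_id := names(sam_paths)[k]]
    obs_all[[k]] <- obs
  }
  obs <- rbindlist(obs_all)
  if (is.null(obs) || !nrow(obs)) {
    out <- data.table(chrom = character(), start = integer(), end = integer(),
                      sample_id = character(), n_reads = integer(), anchor_min = integer())
  } else {
    out <- obs[, .(n_reads = .N, anchor_min = min(anchor)),
               by = .(chrom, start, end, sample_id)]
    setorder(out, chrom, start, end, sample_id)
  }
  attr(out, "rejects") <- rejects
  out[]
}

#' Call candidate micro-exons from pooled observations
#'
#' Intervals whose total read support pooled over all samples is strictly
#' greater than `min_support` become candidates and are classified against
#' the annotation.
#'
#' @param observations Output of [scan_alignments()].
#' @param min_support Total read support must exceed this (default 10, i.e.
#'   11 reads call a candidate and 10 do not).
#' @param genes `gene_models` used for the gene-span containment test (may be
#'   NULL: all non-annotated candidates become novel_intergenic).
#' @param annotated Micro-exon table from [extract_annotated_microexons()]
#'   (may be NULL).
#' @param per_sample When TRUE, require support > `min_support` in every
#'   sample instead of in the pooled total.
#' @return data.table of candidates: interval, `total_support`, per-sample
#'   support collapsed in `n_samples`, `anchor_min`, `annotation_status`
#'   (annotated / novel_in_gene / novel_intergenic), `strand` (the annotated
#'   gene strand where applicable, else "*"), and `near_annotated` — TRUE for
#'   novel candidates within 3 nt of an annotated micro-exon boundary.
#' @export
call_candidates <- function(observations, min_support = 10L, genes = NULL,
                            annotated = NULL, per_sample = FALSE) {
  if (!nrow(observations))
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      strand = character(), length_nt = integer(),
                      total_support = integer(), n_samples = integer(),
                      anchor_min = integer(), annotation_status = character(),
                      gene_id = character(), near_annotated = logical()))
  agg <- observations[, .(total_support = sum(n_reads), n_samples = .N,
                          anchor_min = min(anchor_min),
                          min_sample_support = min(n_reads)),
                      by = .(chrom, start, end)]
  keep <- if (per_sample) agg$min_sample_support > min_support else agg$total_support > min_support
  cand <- agg[keep][, min_sample_support := NULL]
  if (!nrow(cand)) {
    cand[, `:=`(strand = character(), length_nt = integer(),
                annotation_status = character(), gene_id = character(),
                near_annotated = logical())]
    return(cand[])
  }
  cand[, length_nt := end - start + 1L]
  cand[, `:=`(annotation_status = "novel_intergenic", gene_id = NA_character_,
              strand = "*", near_annotated = FALSE)]

  if (!is.null(annotated) && nrow(annotated)) {
    m <- merge(cand[, .(chrom, start, end)], annotated[, .(chrom, start, end, mex_id)],
               by = c("chrom", "start", "end"))
    cand[m, on = c("chrom", "start", "end"), annotation_status := "annotated"]
    # near-miss diagnostics: boundaries within 3 nt but not exact
    for (i in which(cand$annotation_status != "annotated")) {
      near <- annotated[chrom == cand$chrom[i] &
                        abs(start - cand$start[i]) <= 3L & abs(end - cand$end[i]) <= 3L]
      if (nrow(near)) cand[i, near_annotated := TRUE]
    }
  }
  if (!is.null(genes)) {
    g <- genes$genes
    todo <- which(cand$annotation_status != "annotated")
    for (i in todo) {
      hit <- g[chrom == cand$chrom[i] & start <= cand$start[i] & end >= cand$end[i]]
      if (nrow(hit)) cand[i, `:=`(annotation_status = "novel_in_gene",
                                  gene_id = hit$gene_id[1], strand = hit$strand[1])]
    }
    ann_idx <- which(cand$annotation_status == "annotated")
    for (i in ann_idx) {
      hit <- g[chrom == cand$chrom[i] & start <= cand$start[i] & end >= cand$end[i]]
      if (nrow(hit)) cand[i, `:=`(gene_id = hit$gene_id[1], strand = hit$strand[1])]
    }
  }
  setorder(cand, chrom, start, end)
  data.table::setcolorder(cand, c("chrom", "start", "end", "strand", "length_nt",
                                  "total_support", "n_samples", "anchor_min",
                                  "annotation_status", "gene_id", "near_annotated"))
  cand[]
}
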