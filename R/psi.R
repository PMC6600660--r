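#' Build the inclusion/exclusion junction reference library
#'
#' For every internal micro-exon the longest transcript carrying it internally
#' is selected; the inclusion reference is the mature (spliced) sequence of up
#' to `flank` nt upstream, the micro-exon, and up to `flank` nt downstream,
#' truncated at transcript ends; the exclusion reference joins the two flanks
#' directly. Micro-exons whose spliced distance to a neighbouring micro-exon
#' on the same transcript is below `flank` share a `group_id`; each member
#' still gets its own reference pair, with group mates present in both the
#' inclusion and exclusion sequences so that only the member's own junctions
#' discriminate.
#'
#' @param mexs Micro-exon table ([extract_annotated_microexons()]).
#' @param genes `gene_models` with genome sequence.
#' @param flank Flank length in nt (default 100).
#' @return data.table with one row per usable micro-exon: `mex_id`,
#'   `group_id`, `transcript_id`, `up_len`, `mex_len`, `down_len`,
#'   `l_off`/`r_off`/`skip_off` (1-based position of the last base before each
#'   junction), `inclusion_seq`, `exclusion_seq`. Excluded micro-exons (no
#'   flanking exon on one side) are reported in attribute `excluded`.
#' @export
build_junction_library <- function(mexs, genes, flank = 100L) {
  stopifnot(inherits(genes, "gene_models"))
  internal <- mexs[positional_class == "internal"]
  excluded <- data.table(mex_id = character(), reason = character())
  if (!nrow(internal)) {
    out <- data.table(mex_id = character(), group_id = character(),
                      transcript_id = character(), up_len = integer(),
                      mex_len = integer(), down_len = integer(), l_off = integer(),
                      r_off = integer(), skip_off = integer(),
                      inclusion_seq = character(), exclusion_seq = character())
    attr(out, "excluded") <- excluded
    return(out)
  }

  ex <- copy(genes$exons)
  ex[, n_exons := .N, by = transcript_id]
  tx_len <- ex[, .(spliced_len = sum(end - start + 1L)), by = transcript_id]

  # choose, per micro-exon, the longest transcript in which it sits internally
  picks <- rbindlist(lapply(seq_len(nrow(internal)), function(i) {
    m <- internal[i]
    txs <- strsplit(m$transcript_ids, ",")[[1]]
    cand <- ex[transcript_id %in% txs & chrom == m$chrom & start == m$start & end == m$end]
    # internal in transcription order = not rank 1 and not rank n (strand-agnostic)
    cand <- cand[exon_rank > 1L & exon_rank < n_exons]
    if (!nrow(cand)) return(NULL)
    cand <- merge(cand, tx_len, by = "transcript_id")
    setorder(cand, -spliced_len, transcript_id)
    data.table(mex_id = m$mex_id, transcript_id = cand$transcript_id[1],
               chrom = m$chrom, start = m$start, end = m$end, strand = m$strand)
  }))
  no_pick <- setdiff(internal$mex_id, picks$mex_id)
  if (length(no_pick)) {
    excluded <- rbind(excluded, data.table(mex_id = no_pick,
                                           reason = "no transcript with flanking exons on both sides"))
    message(sprintf("junction library: excluded %d micro-exon(s) lacking a flanking exon", length(no_pick)))
  }
  if (!nrow(picks)) {
    out <- build_junction_library(mexs[0], genes, flank)
    attr(out, "excluded") <- excluded
    return(out)
  }

  # spliced coordinates of each picked micro-exon within its transcript
  picks[, c("sp_start", "sp_end", "sp_len") := {
    res <- lapply(seq_len(.N), function(i) {
      e <- ex[transcript_id == picks$transcript_id[i]]
      setorder(e, start)
      if (e$strand[1] == "-") e <- e[rev(seq_len(nrow(e)))]
      w <- e$end - e$start + 1L
      cum <- cumsum(w)
      k <- which(e$start == picks$start[i] & e$end == picks$end[i])
      list(cum[k] - w[k] + 1L, cum[k], sum(w))
    })
    list(vapply(res, `[[`, 1L, 1L), vapply(res, `[[`, 1L, 2L), vapply(res, `[[`, 1L, 3L))
  }]

  # merged groups: same transcript, spliced gap < flank
  setorder(picks, transcript_id, sp_start)
  picks[, group_id := {
    gid <- integer(.N)
    g <- 1L
    if (.N > 1L) for (i in 2:.N) {
      if (sp_start[i] - sp_end[i - 1L] - 1L >= flank) g <- g + 1L
      gid[i] <- g
    }
    gid[1] <- 1L
    cumsum(c(TRUE, diff(gid) != 0L))
  }, by = transcript_id]
  picks[, group_id := paste0(transcript_id, ":g", group_id)]

  sp_cache <- new.env(parent = emptyenv())
  spliced <- function(tx) {
    if (is.null(sp_cache[[tx]])) sp_cache[[tx]] <- transcript_spliced_seq(genes, tx)
    sp_cache[[tx]]
  }

  refs <- picks[, {
    sq <- spliced(transcript_id[1])
    L <- nchar(sq)
    up_len <- pmin(flank, sp_start - 1L)
    down_len <- pmin(flank, L - sp_end)
    mex_len <- sp_end - sp_start + 1L
    incl <- substring(sq, sp_start - up_len, sp_end + down_len)
    excl <- paste0(substring(sq, sp_start - up_len, sp_start - 1L),
                   substring(sq, sp_end + 1L, sp_end + down_len))
    .(mex_id = mex_id, group_id = group_id, transcript_id = transcript_id,
      up_len = up_len, mex_len = mex_len, down_len = down_len,
      l_off = up_len, r_off = up_len + mex_len, skip_off = up_len,
      inclusion_seq = incl, exclusion_seq = excl)
  }, by = .(tx = transcript_id)][, tx := NULL][]
  setorder(refs, mex_id)
  attr(refs, "excluded") <- excluded
  refs[]
}

#' Write the junction library as FASTA with structured headers
#'
#' Headers are `mex_id|incl|l=<l_off>;r=<r_off>` and
#' `mex_id|excl|s=<skip_off>`, matching the reference names expected in SAM
#' alignments consumed by [count_junction_reads()].
#' @param refs Junction references from [build_junction_library()].
#' @param path Output FASTA path.
#' @export
write_junction_fasta <- function(refs, path) {
  lines <- character(0)
  for (i in seq_len(nrow(refs))) {
    lines <- c(lines,
               sprintf(">%s|incl|l=%d;r=%d", refs$mex_id[i], refs$l_off[i], refs$r_off[i]),
               refs$inclusion_seq[i],
               sprintf(">%s|excl|s=%d", refs$mex_id[i], refs$skip_off[i]),
               refs$exclusion_seq[i])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Count junction-spanning reads against the junction library
#'
#' A read increments `R_L`/`R_R` when its alignment to the inclusion
#' reference covers the corresponding junction with at least `min_overhang`
#' aligned nt on both sides, and `R_skipped` analogously on the exclusion
#' reference. A single read may support both inclusion junctions of a short
#' micro-exon. `R_tot = 2 * min(R_L, R_R)` caps inclusion support so an
#' alternative 5'/3' splice site inflating one junction cannot bias the
#' estimate.
#'
#' @param sam_paths Character vector of SAM files of reads aligned to the
#'   junction library (single-end); names are sample ids.
#' @param refs Junction references from [build_junction_library()].
#' @param min_overhang Minimum aligned nt on each side of a junction
#'   (default 3).
#' @param max_mismatches Maximum NM value tolerated (default 2).
#' @return data.table with one row per (mex_id, sample_id): `R_L`, `R_R`,
#'   `R_skipped`, `R_tot`. All library members appear, zero-filled.
#' @export
count_junction_reads <- function(sam_paths, refs, min_overhang = 3L, max_mismatches = 2L) {
  sam_paths <- normalize_alignment_inputs(sam_paths)
  known <- c(paste0(refs$mex_id, "|incl"), paste0(refs$mex_id, "|excl"))
  res <- vector("list", length(sam_paths))
  for (k in seq_along(sam_paths)) {
    aln <- copy(sam_paths[[k]])
    counts <- data.table(mex_id = refs$mex_id, sample_id = names(sam_paths)[k],
                         R_L = 0L, R_R = 0L, R_skipped = 0L)
    if (nrow(aln)) {
      aln[is.na(nm), nm := 0L]
      aln <- aln[is_primary_alignment(flag) & nm <= max_mismatches]
      # strip any offsets annotation appended by write_junction_fasta headers
      aln[, rname := sub("\\|(l|s)=.*$", "", rname)]
      unknown <- setdiff(unique(aln$rname), known)
      if (length(unknown)) {
        warn_mex("skipping %d alignment(s) to unknown reference(s) e.g. '%s'",
                 sum(aln$rname %in% unknown), unknown[1])
        aln <- aln[!rname %in% unknown]
      }
      if (nrow(aln)) {
        blocks <- cigar_ref_blocks(aln$cigar, aln$pos)
        aln[, `:=`(aln_start = vapply(blocks, function(b) min(b[, "start"]), 1L),
                   aln_end = vapply(blocks, function(b) max(b[, "end"]), 1L))]
        aln[, `:=`(mex = sub("\\|(incl|excl)$", "", rname),
                   role = sub("^.*\\|", "", rname))]
        a <- merge(aln, refs[, .(mex_id, l_off, r_off, skip_off)],
                   by.x = "mex", by.y = "mex_id")
        covers <- function(j, s, e) s <= j - min_overhang + 1L & e >= j + min_overhang
        cl <- a[role == "incl" & covers(l_off, aln_start, aln_end), .N, by = mex]
        cr <- a[role == "incl" & covers(r_off, aln_start, aln_end), .N, by = mex]
        cs <- a[role == "excl" & covers(skip_off, aln_start, aln_end), .N, by = mex]
        counts[cl, on = c(mex_id = "mex"), R_L := i.N]
        counts[cr, on = c(mex_id = "mex"), R_R := i.N]
        counts[cs, on = c(mex_id = "mex"), R_skipped := i.N]
      }
    }
    res[[k]] <- counts
  }
  out <- rbindlist(res)
  out[, R_tot := 2L * pmin(R_L, R_R)]
  setorder(out, mex_id, sample_id)
  out[]
}

#' Compute percent-spliced-in from junction counts
#'
#' `PSI = R_tot / (R_tot + R_skipped)` with `R_tot = 2 * min(R_L, R_R)`. The
#' value is missing unless the coverage rule holds: `R_L + R_R >= min_cov` or
#' `R_skipped >= min_cov` (and `R_tot + R_skipped > 0`).
#'
#' @param counts data.table with `R_L`, `R_R`, `R_skipped` (and usually
#'   `mex_id`, `sample_id`); a `R_tot` column is (re)computed.
#' @param min_cov Coverage floor (default 10).
#' @return The input plus `R_tot`, `psi` (NA when missing) and
#'   `splice_class` per [classify_splicing()]. Column `unit_id` mirrors
#'   `sample_id` when present.
#' @export
compute_psi <- function(counts, min_cov = 10L) {
  out <- as.data.table(copy(counts))
  stopifnot(all(c("R_L", "R_R", "R_skipped") %in% names(out)))
  if (any(out$R_L < 0 | out$R_R < 0 | out$R_skipped < 0))
    stop_mex("junction counts must be non-negative")
  out[, R_tot := 2L * pmin(R_L, R_R)]
  out[, psi := ifelse(((R_L + R_R >= min_cov) | (R_skipped >= min_cov)) &
                        (R_tot + R_skipped > 0),
                      R_tot / (R_tot + R_skipped), NA_real_)]
  out[, splice_class := classify_splicing(psi)]
  if ("sample_id" %in% names(out) && !"unit_id" %in% names(out))
    out[, unit_id := sample_id]
  out[]
}

#' Classify splicing status from PSI
#'
#' @param psi Numeric vector of PSI values (NA = missing).
#' @param cs_min PSI at or above this is constitutive (default 0.9).
#' @param as_min PSI at or above this (and below `cs_min`) is alternative
#'   (default 0.1); below it the micro-exon is lowly included.
#' @return Character vector over {"CS", "AS", "low", "missing"}.
#' @export
classify_splicing <- function(psi, cs_min = 0.9, as_min = 0.1) {
  ifelse(is.na(psi), "missing",
         ifelse(psi >= cs_min, "CS", ifelse(psi >= as_min, "AS", "low")))
}

#' Merge PSI values of two biological replicates
#'
#' Vectorized three-case rule: a value present in only one replicate is used;
#' two present values closer than `max_delta` (absolute PSI units, strict)
#' average; two present values at least `max_delta` apart become missing.
#'
#' @param a,b Numeric PSI vectors (NA = missing), or two PSI record tables
#'   with columns `mex_id` and `psi` covering the same micro-exons.
#' @param max_delta Maximum tolerated absolute replicate difference
#'   (default 0.10).
#' @param unit_id Label for the merged unit (table interface only).
#' @return Merged numeric vector, or a merged PSI record table with
#'   `splice_class` recomputed.
#' @export
merge_replicates <- function(a, b, max_delta = 0.10, unit_id = "merged") {
  if (is.numeric(a) && is.numeric(b)) {
    if (length(a) != length(b)) stop_mex("replicate vectors differ in length")
    check_fraction(a, "psi"); check_fraction(b, "psi")
    # round the difference so the strict < at the 0.10 boundary is not
    # defeated by binary floating point (|0.5 - 0.6| < 0.1 in doubles)
    d <- round(abs(a - b), 9)
    out <- ifelse(is.na(a), b,
                  ifelse(is.na(b), a,
                         ifelse(d < max_delta, (a + b) / 2, NA_real_)))
    return(out)
  }
  a <- as.data.table(a); b <- as.data.table(b)
  if (!setequal(a$mex_id, b$mex_id))
    stop_mex("mismatched mex_id sets between replicates (e.g. '%s')",
             setdiff(union(a$mex_id, b$mex_id), intersect(a$mex_id, b$mex_id))[1])
  m <- merge(a[, .(mex_id, psi_a = psi)], b[, .(mex_id, psi_b = psi)], by = "mex_id")
  m[, psi := merge_replicates(psi_a, psi_b, max_delta)]
  m[, `:=`(psi_a = NULL, psi_b = NULL)]
  m[, unit_id := unit_id]
  m[, splice_class := classify_splicing(psi)]
  m[]
}

#' Per-tissue expressed, tissue-specific and overlap sets of micro-exons
#'
#' A micro-exon is expressed in a tissue when its merged PSI is at least
#' `min_psi` in at least `min_samples` of the tissue's sample units.
#'
#' @param psi_long data.table with columns `mex_id`, `unit_id`, `tissue`,
#'   `psi` (merged-replicate units).
#' @param min_psi Expression floor on PSI (default 0.10).
#' @param min_samples Minimum qualifying units per tissue (default 2).
#' @param tissues Optional declared tissue universe; a unit labelled outside
#'   it raises an error.
#' @return list with `expressed` (wide logical table micro-exon x tissue),
#'   `overlap` (counts per tissue-combination membership pattern),
#'   `specific` (named list of tissue-specific micro-exon id vectors).
#' @export
tissue_expression_sets <- function(psi_long, min_psi = 0.10, min_samples = 2L,
                                   tissues = NULL) {
  psi_long <- as.data.table(psi_long)
  stopifnot(all(c("mex_id", "tissue", "psi") %in% names(psi_long)))
  if (!is.null(tissues)) {
    unknown <- setdiff(unique(psi_long$tissue), tissues)
    if (length(unknown)) stop_mex("unknown tissue label '%s'", unknown[1])
  } else tissues <- sort(unique(psi_long$tissue))
  ex <- psi_long[, .(expressed = sum(!is.na(psi) & psi >= min_psi) >= min_samples),
                 by = .(mex_id, tissue)]
  wide <- data.table::dcast(ex, mex_id ~ tissue, value.var = "expressed", fill = FALSE)
  for (tt in setdiff(tissues, names(wide))) wide[, (tt) := FALSE]
  data.table::setcolorder(wide, c("mex_id", tissues))
  pat <- apply(as.matrix(wide[, ..tissues]), 1L, function(r)
    paste(tissues[r], collapse = "+"))
  pat[pat == ""] <- "(none)"
  overlap <- data.table(combination = pat)[, .(count = .N), by = combination]
  setorder(overlap, -count, combination)
  n_tis <- rowSums(as.matrix(wide[, ..tissues]))
  specific <- lapply(tissues, function(tt)
    wide$mex_id[n_tis == 1L & wide[[tt]]])
  names(specific) <- tissues
  list(expressed = wide[], overlap = overlap[], specific = specific)
}
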