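# Minimal SAM text I/O. The package consumes alignments produced upstream (or
# by its own simulator); only the mandatory columns plus the NM tag are used.
# BAM users can pipe through `samtools view`.

#' Read a SAM file into a data.table
#'
#' @param path Path to a SAM file (plain text).
#' @return data.table with columns qname, flag, rname, pos, mapq, cigar, seq
#'   and nm (the NM:i mismatch tag; NA when absent).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop_mex("SAM file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.table(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      seq = character(), nm = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 11L
  if (any(bad)) {
    warn_mex("skipping %d unparseable SAM line(s)", sum(bad))
    fields <- fields[!bad]
  }
  if (!length(fields))
    return(data.table(qname = character(), flag = integer(), rname = character(),
                      pos = integer(), mapq = integer(), cigar = character(),
                      seq = character(), nm = integer()))
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, 1L)
  dt <- data.table(
    qname = vapply(fields, `[[`, "", 1L),
    flag  = as.integer(vapply(fields, `[[`, "", 2L)),
    rname = vapply(fields, `[[`, "", 3L),
    pos   = as.integer(vapply(fields, `[[`, "", 4L)),
    mapq  = as.integer(vapply(fields, `[[`, "", 5L)),
    cigar = vapply(fields, `[[`, "", 6L),
    seq   = vapply(fields, `[[`, "", 10L),
    nm = nm
  )
  attr(dt, "n_rejected") <- sum(bad)
  dt[]
}

#' Write alignments as SAM
#'
#' @param aln data.table with qname, flag, rname, pos, mapq, cigar, seq and
#'   optionally nm; missing optional fields get defaults.
#' @param path Output path.
#' @param ref_lengths Named integer vector of reference lengths for the @SQ
#'   header lines.
#' @export
write_sam <- function(aln, path, ref_lengths) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)))
  nm <- if ("nm" %in% names(aln)) aln$nm else rep(0L, nrow(aln))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                  aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                  aln$cigar, aln$seq, nm)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Parse CIGAR strings into per-alignment reference blocks (1-based inclusive).
# M/=/X/D consume reference within a block; N splits blocks; I/S/H/P are
# ignored on the reference. Returns a list of 2-column matrices (start, end).
cigar_ref_blocks <- function(cigar, pos) {
  ops_list <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  Map(function(ops, p) {
    len <- as.integer(sub("[A-Z=]$", "", ops))
    op <- substring(ops, nchar(ops), nchar(ops))
    starts <- integer(0); ends <- integer(0)
    cur_start <- p; cur <- p
    open <- FALSE
    for (i in seq_along(op)) {
      if (op[i] %in% c("M", "=", "X", "D")) {
        if (!open) { cur_start <- cur; open <- TRUE }
        cur <- cur + len[i]
      } else if (op[i] == "N") {
        if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur - 1L); open <- FALSE }
        cur <- cur + len[i]
      }
      # I/S/H/P: no reference advance
    }
    if (open) { starts <- c(starts, cur_start); ends <- c(ends, cur - 1L) }
    cbind(start = starts, end = ends)
  }, ops_list, pos)
}

FLAG_UNMAPPED <- 0x4L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

# primary, mapped, non-supplementary
is_primary_alignment <- function(flag) {
  bitwAnd(flag, bitwOr(bitwOr(FLAG_UNMAPPED, FLAG_SECONDARY), FLAG_SUPPLEMENTARY)) == 0L
}

# alignment inputs may be SAM paths or in-memory alignment tables; normalize
# to a named list of data.tables
normalize_alignment_inputs <- function(x) {
  if (is.data.frame(x)) x <- list(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- tools::file_path_sans_ext(basename(x))
    x <- as.list(x)
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    names(x) <- sprintf("s%d", seq_along(x))
  lapply(x, function(e) if (is.character(e)) read_sam(e) else as.data.table(e))
}
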