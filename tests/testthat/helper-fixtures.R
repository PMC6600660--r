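# Hand-built toy annotation fixture: two genes on one chromosome, written as
# real GFF3 + FASTA files so the I/O path is exercised.
#
# gene GA (+): tx GA.1 exons [101,112] (12 nt UTR first), [301,700],
#   [1001,1012] (12 nt internal, fully CDS), [1301,1800];
#   tx GA.2 exons [301,700], [1001,1012] (last here -> class conflict).
# gene GB (-): tx GB.1 exons [2101,2400], [2601,2646]
#   (46 nt, first in transcription order on minus strand), fully CDS.
toy_annotation_files <- function(dir = tempfile("toyann")) {
  dir.create(dir)
  set.seed(99L)
  chr_seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">chrT", chr_seq), fasta)
  g <- c(
    "##gff-version 3",
    "chrT\ttoy\tgene\t101\t1800\t.\t+\t.\tID=GA",
    "chrT\ttoy\tmRNA\t101\t1800\t.\t+\t.\tID=GA.1;Parent=GA",
    "chrT\ttoy\texon\t101\t112\t.\t+\t.\tParent=GA.1",
    "chrT\ttoy\texon\t301\t700\t.\t+\t.\tParent=GA.1",
    "chrT\ttoy\texon\t1001\t1012\t.\t+\t.\tParent=GA.1",
    "chrT\ttoy\texon\t1301\t1800\t.\t+\t.\tParent=GA.1",
    "chrT\ttoy\tCDS\t401\t700\t.\t+\t0\tParent=GA.1",
    "chrT\ttoy\tCDS\t1001\t1012\t.\t+\t0\tParent=GA.1",
    "chrT\ttoy\tCDS\t1301\t1500\t.\t+\t0\tParent=GA.1",
    "chrT\ttoy\tmRNA\t301\t1012\t.\t+\t.\tID=GA.2;Parent=GA",
    "chrT\ttoy\texon\t301\t700\t.\t+\t.\tParent=GA.2",
    "chrT\ttoy\texon\t1001\t1012\t.\t+\t.\tParent=GA.2",
    "chrT\ttoy\tCDS\t401\t700\t.\t+\t0\tParent=GA.2",
    "chrT\ttoy\tCDS\t1001\t1012\t.\t+\t0\tParent=GA.2",
    "chrT\ttoy\tgene\t2101\t2646\t.\t-\t.\tID=GB",
    "chrT\ttoy\tmRNA\t2101\t2646\t.\t-\t.\tID=GB.1;Parent=GB",
    "chrT\ttoy\texon\t2101\t2400\t.\t-\t.\tParent=GB.1",
    "chrT\ttoy\texon\t2601\t2646\t.\t-\t.\tParent=GB.1",
    "chrT\ttoy\tCDS\t2101\t2400\t.\t-\t2\tParent=GB.1",
    "chrT\ttoy\tCDS\t2601\t2646\t.\t-\t0\tParent=GB.1"
  )
  gff <- file.path(dir, "toy.gff3")
  writeLines(g, gff)
  list(gff3 = gff, fasta = fasta, chr_seq = chr_seq)
}

# independent PSI oracle: scalar, straight from the two published equations
# plus the coverage-missingness rule
psi_oracle <- function(rl, rr, rs, min_cov = 10) {
  rtot <- 2 * min(rl, rr)
  if (!((rl + rr >= min_cov) || (rs >= min_cov))) return(NA_real_)
  if (rtot + rs == 0) return(NA_real_)
  rtot / (rtot + rs)
}

# independent replicate-merge oracle; the rounding emulates exact decimal
# arithmetic at the strict 0.10 boundary
merge_oracle <- function(a, b, delta = 0.10) {
  if (is.na(a) && is.na(b)) return(NA_real_)
  if (is.na(a)) return(b)
  if (is.na(b)) return(a)
  if (round(abs(a - b), 9) < delta) return((a + b) / 2)
  NA_real_
}

# brute-force middle-block enumeration over a SAM table (detection oracle);
# written against the rule text, independent of scan_alignments internals
detect_oracle <- function(aln, min_len = 3, max_len = 51, min_anchor = 6,
                          max_mismatches = 2, min_mapq = 1) {
  out <- list()
  for (i in seq_len(nrow(aln))) {
    flag <- aln$flag[i]
    if (bitwAnd(flag, 4L) != 0L || bitwAnd(flag, 256L) != 0L ||
        bitwAnd(flag, 2048L) != 0L) next
    if (aln$mapq[i] < min_mapq) next
    nm <- aln$nm[i]; if (is.na(nm)) nm <- 0L
    if (nm >= max_mismatches) next
    ops <- regmatches(aln$cigar[i], gregexpr("\\d+[A-Z=]", aln$cigar[i]))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    pos <- aln$pos[i]
    starts <- c(); ends <- c(); cur <- pos; open_start <- NA
    for (j in seq_along(op)) {
      if (op[j] %in% c("M", "=", "X", "D")) {
        if (is.na(open_start)) open_start <- cur
        cur <- cur + lens[j]
      } else if (op[j] == "N") {
        starts <- c(starts, open_start); ends <- c(ends, cur - 1L)
        open_start <- NA; cur <- cur + lens[j]
      }
    }
    if (!is.na(open_start)) { starts <- c(starts, open_start); ends <- c(ends, cur - 1L) }
    nb <- length(starts)
    if (nb < 3) next
    w <- ends - starts + 1L
    for (k in 2:(nb - 1)) {
      if (w[k] >= min_len && w[k] <= max_len &&
          w[k - 1] >= min_anchor && w[k + 1] >= min_anchor)
        out[[length(out) + 1L]] <- data.frame(chrom = aln$rname[i],
                                              start = starts[k], end = ends[k])
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer()))
  do.call(rbind, out)
}

# small ready-made simulation shared by several tests
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_genome_annotation(
        sim_config(seed = 42, n_genes = 10, depth = 60, novel_fraction = 0.2))
    cache
  }
})
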