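# Deterministic synthetic-data generator. The stated world mirrors the study
# design the pipeline targets: strand-specific 101-nt reads over annotated
# splice junctions of a compact multi-exon genome, four tissues with two
# biological replicates, ~59% frame-shifting micro-exon lengths, ~60%
# constitutive inclusion, one third of planted micro-exons left out of the
# annotation, and planted gene ages at 54.2% old / 13.2% young.

#' Simulation configuration
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param n_genes Number of genes (one planted micro-exon each).
#' @param microexon_length_set Candidate micro-exon lengths in nt (3-51).
#' @param frame_shift_fraction Fraction of planted micro-exons whose length
#'   is not a multiple of three (default 0.593).
#' @param true_psi Optional numeric vector (recycled over genes) of true
#'   inclusion levels; when NULL, ~60% of micro-exons draw PSI from
#'   U(0.92, 1) (constitutive) and the rest from U(0.15, 0.85).
#' @param cs_fraction Fraction of constitutive micro-exons used when
#'   `true_psi` is NULL (default 0.6).
#' @param read_length Read length in nt (default 101).
#' @param depth Junction-spanning reads per micro-exon, tissue and replicate
#'   (default 60).
#' @param n_tissues,n_conditions,n_replicates Design size (defaults 4
#'   tissues, 2 growth conditions, 2 biological replicates; the merged
#'   replicate pair is the condition unit).
#' @param replicate_noise_sd Replicate-level PSI jitter (truncated normal,
#'   default 0.02).
#' @param intron_range Intron length bounds in nt (default 60-500).
#' @param novel_fraction Fraction of planted micro-exons omitted from the
#'   GFF3 (novel-detection truth; default 1/3).
#' @param min_anchor Anchor length used when placing spliced genome reads
#'   (default 6).
#' @param old_fraction,young_fraction Planted gene-age proportions
#'   (defaults 0.542 / 0.132).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, microexon_length_set = 3:51,
                       frame_shift_fraction = 0.593, true_psi = NULL,
                       cs_fraction = 0.6, read_length = 101L, depth = 60L,
                       n_tissues = 4L, n_conditions = 2L, n_replicates = 2L,
                       replicate_noise_sd = 0.02, intron_range = c(60L, 500L),
                       novel_fraction = 1 / 3, min_anchor = 6L,
                       old_fraction = 0.542, young_fraction = 0.132) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              microexon_length_set = as.integer(microexon_length_set),
              frame_shift_fraction = frame_shift_fraction, true_psi = true_psi,
              cs_fraction = cs_fraction, read_length = as.integer(read_length),
              depth = as.integer(depth), n_tissues = as.integer(n_tissues),
              n_conditions = as.integer(n_conditions),
              n_replicates = as.integer(n_replicates),
              replicate_noise_sd = replicate_noise_sd,
              intron_range = as.integer(intron_range),
              novel_fraction = novel_fraction, min_anchor = as.integer(min_anchor),
              old_fraction = old_fraction, young_fraction = young_fraction)
  check_fraction(c(cfg$frame_shift_fraction, cfg$cs_fraction, cfg$novel_fraction,
                   cfg$old_fraction, cfg$young_fraction, cfg$true_psi),
                 "sim_config fractions")
  if (any(cfg$microexon_length_set < 3L | cfg$microexon_length_set > 51L))
    stop_mex("microexon_length_set must lie in [3,51]")
  if (cfg$read_length <= 2L * cfg$min_anchor)
    stop_mex("read_length must exceed 2*min_anchor")
  if (cfg$depth < 0L) stop_mex("depth must be >= 0")
  if (length(cfg$intron_range) != 2L || cfg$intron_range[1] > cfg$intron_range[2] ||
      cfg$intron_range[1] < 4L)
    stop_mex("invalid intron_range")
  structure(cfg, class = "sim_config")
}

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

random_codons <- function(n) paste(sample(NON_STOP_CODONS, n, replace = TRUE), collapse = "")

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Simulate a toy genome, annotation and planted micro-exon ground truth
#'
#' Genes carry 3-8 exons with canonical GT..AG introns and exactly one
#' planted internal micro-exon; flanking (first/last) exons are at least
#' 120 nt and other exons 80-300 nt so junction windows are always wide
#' enough for 101-nt reads. Half the genes sit on the minus strand. A
#' configurable fraction of micro-exons is left out of the emitted GFF3 (but
#' present in simulated reads) as novel-detection truth. Fully deterministic
#' under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `mex_sim`: list with `cfg`, `genome`
#'   (DNAStringSet), `genes` (annotated `gene_models`), `genes_true` (gene
#'   models including unannotated micro-exons), `truth` (one row per planted
#'   micro-exon: interval, length, frame class, annotated flag, true PSI,
#'   planted phylostratum) and the per-gene `blueprint` used to rebuild
#'   collinear partners.
#' @export
simulate_genome_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  n <- cfg$n_genes
  inset <- cfg$microexon_length_set[cfg$microexon_length_set %% 3L == 0L]
  shset <- cfg$microexon_length_set[cfg$microexon_length_set %% 3L != 0L]

  n_shift <- round(cfg$frame_shift_fraction * n)
  shift_flags <- rep(FALSE, n)
  if (n_shift > 0) shift_flags[sample.int(n, n_shift)] <- TRUE

  # planted gene ages
  n_old <- round(cfg$old_fraction * n); n_young <- round(cfg$young_fraction * n)
  ages <- c(sample(1:3, n_old, replace = TRUE),
            sample(11:13, n_young, replace = TRUE),
            sample(4:10, n - n_old - n_young, replace = TRUE))
  ages <- ages[sample.int(n)]

  # true inclusion levels
  if (!is.null(cfg$true_psi)) {
    psis <- rep_len(cfg$true_psi, n)
  } else {
    cs <- stats::runif(n) < cfg$cs_fraction
    psis <- ifelse(cs, stats::runif(n, 0.92, 1), stats::runif(n, 0.15, 0.85))
  }
  annotated_flags <- stats::runif(n) >= cfg$novel_fraction

  blueprint <- vector("list", n)
  for (g in seq_len(n)) {
    n_ex <- sample(3:8, 1L)
    mex_idx <- if (n_ex == 3L) 2L else sample(2:(n_ex - 1L), 1L)
    lens <- integer(n_ex)
    lens[1] <- sample(120:300, 1L)
    lens[n_ex] <- sample(120:300, 1L)
    if (n_ex > 2L) lens[2:(n_ex - 1L)] <- sample(80:300, n_ex - 2L, replace = TRUE)
    pick <- if (shift_flags[g]) shset else inset
    if (!length(pick)) pick <- cfg$microexon_length_set
    lens[mex_idx] <- if (length(pick) == 1L) pick else sample(pick, 1L)
    pad <- (3L - sum(lens) %% 3L) %% 3L
    lens[n_ex] <- lens[n_ex] + pad
    cds_seq <- paste0("ATG", random_codons(sum(lens) / 3L - 1L))
    cuts <- cumsum(lens)
    exon_seqs <- substring(cds_seq, c(1L, cuts[-n_ex] + 1L), cuts)
    intron_lens <- sample(cfg$intron_range[1]:cfg$intron_range[2], n_ex - 1L, replace = TRUE)
    intron_seqs <- vapply(intron_lens, function(L)
      paste0("GT", random_dna(L - 4L), "AG"), "")
    blueprint[[g]] <- list(
      gene_id = sprintf("G%03d", g), tx_id = sprintf("G%03d.t1", g),
      chrom = if (g <= ceiling(n / 2)) "chr1" else "chr2",
      strand = if (g %% 2L == 0L) "-" else "+",
      exon_seqs = exon_seqs, intron_seqs = intron_seqs, mex_idx = mex_idx,
      annotated = annotated_flags[g], true_psi = psis[g], ps_level = ages[g],
      frame_class = if (lens[mex_idx] %% 3L == 0L) "in_frame" else "frame_shifting")
  }
  assemble_sim(cfg, blueprint)
}

# lay out gene blueprints on chromosomes and build all derived objects
assemble_sim <- function(cfg, blueprint, spacer = 300L) {
  set.seed(derive_seed(cfg$seed, 2L))
  chroms <- unique(vapply(blueprint, `[[`, "", "chrom"))
  chrom_seq <- stats::setNames(vector("list", length(chroms)), chroms)
  offset <- stats::setNames(rep(0L, length(chroms)), chroms)
  truth_rows <- list(); gff_rows <- list()
  genes_t <- list(); txs_t <- list(); exons_true <- list(); exons_annot <- list()
  cds_true <- list(); cds_annot <- list()

  for (g in seq_along(blueprint)) {
    bp <- blueprint[[g]]
    n_ex <- length(bp$exon_seqs)
    if (length(bp$intron_seqs) != n_ex - 1L)
      stop_mex("gene '%s': %d exons need %d introns", bp$gene_id, n_ex, n_ex - 1L)
    segs <- character(2L * n_ex - 1L)
    segs[seq(1L, 2L * n_ex - 1L, 2L)] <- bp$exon_seqs
    if (n_ex > 1L) segs[seq(2L, 2L * n_ex - 2L, 2L)] <- bp$intron_seqs
    tx_seq <- paste(segs, collapse = "")
    L <- nchar(tx_seq)
    gstart <- offset[[bp$chrom]] + spacer + 1L
    offset[[bp$chrom]] <- gstart + L - 1L
    chrom_seq[[bp$chrom]] <- c(chrom_seq[[bp$chrom]],
                               random_dna(spacer),
                               if (bp$strand == "+") tx_seq else reverse_complement(tx_seq))

    seg_len <- nchar(segs)
    seg_end <- cumsum(seg_len); seg_start <- seg_end - seg_len + 1L
    ex_i <- seq(1L, 2L * n_ex - 1L, 2L)
    tx_s <- seg_start[ex_i]; tx_e <- seg_end[ex_i]  # exon spans, tx coords
    if (bp$strand == "+") {
      gs <- gstart + tx_s - 1L; ge <- gstart + tx_e - 1L
    } else {
      gs <- gstart + (L - tx_e); ge <- gstart + (L - tx_s)
    }
    ex_tab <- data.table(transcript_id = bp$tx_id, chrom = bp$chrom,
                         strand = bp$strand, start = gs, end = ge,
                         tx_order = seq_len(n_ex))
    genes_t[[g]] <- data.table(gene_id = bp$gene_id, chrom = bp$chrom,
                               strand = bp$strand, start = gstart, end = gstart + L - 1L)
    txs_t[[g]] <- data.table(transcript_id = bp$tx_id, gene_id = bp$gene_id,
                             chrom = bp$chrom, strand = bp$strand,
                             start = gstart, end = gstart + L - 1L)
    phases <- function(lens) {
      cum <- cumsum(c(0L, lens[-length(lens)]))
      (3L - cum %% 3L) %% 3L
    }
    full_lens <- tx_e - tx_s + 1L
    exons_true[[g]] <- copy(ex_tab)
    cds_true[[g]] <- copy(ex_tab)[, phase := phases(full_lens)]
    keep <- if (bp$annotated) seq_len(n_ex) else setdiff(seq_len(n_ex), bp$mex_idx)
    ann <- ex_tab[tx_order %in% keep]
    exons_annot[[g]] <- copy(ann)
    cds_annot[[g]] <- copy(ann)[, phase := phases(full_lens[keep])]

    truth_rows[[g]] <- data.table(
      gene_id = bp$gene_id, transcript_id = bp$tx_id, chrom = bp$chrom,
      strand = bp$strand, mex_exon_idx = bp$mex_idx,
      start = gs[bp$mex_idx], end = ge[bp$mex_idx],
      length_nt = full_lens[bp$mex_idx], frame_class = bp$frame_class,
      annotated = bp$annotated, true_psi = bp$true_psi, ps_level = bp$ps_level)
  }

  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, "", collapse = ""))
  names(genome) <- chroms
  drop_order <- function(x) {
    x <- rbindlist(x); x[, tx_order := NULL]; x
  }
  genes_tab <- rbindlist(genes_t); txs_tab <- rbindlist(txs_t)
  genes_annot <- finalize_gene_models(genes_tab, txs_tab, drop_order(exons_annot),
                                      drop_order(cds_annot), genome)
  genes_true <- finalize_gene_models(copy(genes_tab), copy(txs_tab),
                                     drop_order(exons_true), drop_order(cds_true), genome)
  truth <- rbindlist(truth_rows)
  truth[, mex_id := sprintf("%s:%s:%d-%d", gene_id, chrom, start, end)]
  structure(list(cfg = cfg, genome = genome, genes = genes_annot,
                 genes_true = genes_true, truth = truth, blueprint = blueprint),
            class = "mex_sim")
}

#' @export
print.mex_sim <- function(x, ...) {
  cat(sprintf("mex_sim: %d genes on %d chromosome(s); %d planted micro-exons (%d annotated)\n",
              nrow(x$truth), length(x$genome), nrow(x$truth), sum(x$truth$annotated)))
  invisible(x)
}

#' Write a simulated genome, annotation and truth table to a directory
#' @param sim A `mex_sim` object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa"); gff <- file.path(dir, "annotation.gff3")
  tr <- file.path(dir, "truth.tsv")
  writeLines(as.vector(rbind(paste0(">", names(sim$genome)),
                             as.character(sim$genome))), fa)
  write_gff3(sim$genes, gff)
  fwrite(sim$truth, tr, sep = "\t", quote = FALSE)
  c(fasta = fa, gff3 = gff, truth = tr)
}

#' Write gene models as GFF3
#' @param genes A `gene_models` object.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  rows <- character(0)
  fmt <- function(chrom, type, s, e, strand, phase, attr)
    sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t%s\t%s", chrom, type, s, e, strand, phase, attr)
  gt <- genes$genes; tt <- genes$transcripts
  for (i in seq_len(nrow(gt))) {
    gid <- gt$gene_id[i]
    rows <- c(rows, fmt(gt$chrom[i], "gene", gt$start[i], gt$end[i], gt$strand[i], ".",
                        sprintf("ID=%s", gid)))
    txs <- tt[gene_id == gid]
    for (j in seq_len(nrow(txs))) {
      tid <- txs$transcript_id[j]
      rows <- c(rows, fmt(txs$chrom[j], "mRNA", txs$start[j], txs$end[j], txs$strand[j], ".",
                          sprintf("ID=%s;Parent=%s", tid, gid)))
      ex <- genes$exons[transcript_id == tid]
      for (k in seq_len(nrow(ex)))
        rows <- c(rows, fmt(ex$chrom[k], "exon", ex$start[k], ex$end[k], ex$strand[k], ".",
                            sprintf("Parent=%s", tid)))
      cd <- genes$cds[transcript_id == tid]
      for (k in seq_len(nrow(cd)))
        rows <- c(rows, fmt(cd$chrom[k], "CDS", cd$start[k], cd$end[k], cd$strand[k],
                            as.character(cd$phase[k]), sprintf("Parent=%s", tid)))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

# spliced coordinates of the planted micro-exon within its (true) transcript
mex_spliced_coords <- function(sim, gene_id) {
  t_idx <- which(sim$truth$gene_id == gene_id)
  tr <- sim$truth[t_idx]
  e_idx <- which(sim$genes_true$exons$transcript_id == tr$transcript_id)
  ex <- sim$genes_true$exons[e_idx]
  setorder(ex, start)
  if (tr$strand == "-") ex <- ex[rev(seq_len(nrow(ex)))]
  w <- ex$end - ex$start + 1L
  cum <- cumsum(w)
  k <- which(ex$start == tr$start & ex$end == tr$end)
  list(ex = ex, w = w, s = cum[k] - w[k] + 1L, e = cum[k], L = sum(w), k = k)
}

# map a transcript-coordinate interval to genomic blocks (ascending)
tx_interval_to_blocks <- function(ex, w, t1, t2) {
  cum <- cumsum(w); cum0 <- cum - w
  out <- list()
  for (i in seq_len(nrow(ex))) {
    a <- max(t1, cum0[i] + 1L); b <- min(t2, cum[i])
    if (a > b) next
    if (ex$strand[i] == "+") {
      gs <- ex$start[i] + (a - cum0[i] - 1L); ge <- ex$start[i] + (b - cum0[i] - 1L)
    } else {
      gs <- ex$end[i] - (b - cum0[i] - 1L); ge <- ex$end[i] - (a - cum0[i] - 1L)
    }
    out[[length(out) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

genome_read_record <- function(sim, gene_id, qname, t1, t2, sc = NULL) {
  if (is.null(sc)) sc <- mex_spliced_coords(sim, gene_id)
  chrom <- sc$ex$chrom[1]
  chrom_str <- as.character(sim$genome[[chrom]])
  r <- build_spliced_read(sc, chrom_str, t1, t2)
  data.table(qname = qname, flag = 0L, rname = chrom, pos = r$pos,
             mapq = 60L, cigar = r$cigar, seq = r$seq, nm = 0L)
}

# cigar/seq/pos for one read over (possibly several) transcript intervals;
# t_pairs is a list of c(t1, t2) spans in transcript coordinates
build_spliced_read <- function(sc, chrom_str, ..., t_pairs = NULL) {
  spans <- t_pairs %||% list(c(..1, ..2))
  blocks <- do.call(rbind, lapply(spans, function(p)
    tx_interval_to_blocks(sc$ex, sc$w, p[1], p[2])))
  blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  widths <- blocks[, 2] - blocks[, 1] + 1L
  nb <- nrow(blocks)
  cig <- sprintf("%dM", widths)
  if (nb > 1L) {
    gaps <- sprintf("%dN", blocks[-1L, 1] - blocks[-nb, 2] - 1L)
    cig <- c(rbind(cig[-nb], gaps), cig[nb])
  }
  list(pos = blocks[1, 1],
       cigar = paste(cig, collapse = ""),
       seq = paste(substring(chrom_str, blocks[, 1], blocks[, 2]), collapse = ""))
}

#' Emit genome-aligned spliced reads over one planted micro-exon
#'
#' Low-level generator used by [simulate_junction_reads()] and by threshold
#' tests: emits `n` inclusion reads whose left anchor is exactly `anchor` nt
#' (3-block gap-aware alignments spanning the whole micro-exon), or skip
#' reads when `include = FALSE`.
#'
#' @param sim A `mex_sim`.
#' @param gene_id Gene whose micro-exon to cover.
#' @param n Number of reads.
#' @param anchor Exact left-anchor length in nt; NULL draws anchors uniformly
#'   from the conforming range (both anchors >= `sim$cfg$min_anchor`).
#' @param include Emit inclusion (TRUE) or exclusion/skip (FALSE) reads.
#' @param sample_id Used in read names only.
#' @return data.table of SAM records ([write_sam()] layout).
#' @export
sim_reads_for_mex <- function(sim, gene_id, n, anchor = NULL, include = TRUE,
                              sample_id = "s1") {
  if (n <= 0L) return(NULL)
  cfg <- sim$cfg
  sc <- mex_spliced_coords(sim, gene_id)
  chrom <- sc$ex$chrom[1]
  chrom_str <- as.character(sim$genome[[chrom]])
  RL <- cfg$read_length
  mex_len <- sc$e - sc$s + 1L
  up_ex <- sc$w[sc$k - 1L]; down_ex <- sc$w[sc$k + 1L]
  if (include) {
    if (RL < mex_len + 2L * cfg$min_anchor) {
      warn_mex("read length %d cannot span micro-exon of %d nt with both anchors; emitting single-junction reads",
               RL, mex_len)
      a_lo <- max(cfg$min_anchor, RL - mex_len - down_ex)
      a_hi <- min(up_ex, RL - cfg$min_anchor)
    } else {
      a_lo <- max(cfg$min_anchor, RL - mex_len - down_ex)
      a_hi <- min(up_ex, RL - mex_len - cfg$min_anchor)
    }
    anchors <- if (!is.null(anchor)) rep(as.integer(anchor), n)
               else sample(a_lo:a_hi, n, replace = TRUE)
    spans <- lapply(anchors, function(a) {
      t1 <- sc$s - a
      list(c(t1, min(t1 + RL - 1L, sc$L)))
    })
    tag <- "inc"
  } else {
    a_lo <- max(cfg$min_anchor, RL - down_ex)
    a_hi <- min(up_ex, RL - cfg$min_anchor)
    anchors <- if (!is.null(anchor)) rep(as.integer(anchor), n)
               else sample(a_lo:a_hi, n, replace = TRUE)
    spans <- lapply(anchors, function(a)
      list(c(sc$s - a, sc$s - 1L),
           c(sc$e + 1L, min(sc$e + (RL - a), sc$L))))
    tag <- "exc"
  }
  pos <- integer(n); cig <- character(n); sq <- character(n)
  for (i in seq_len(n)) {
    r <- build_spliced_read(sc, chrom_str, t_pairs = spans[[i]])
    pos[i] <- r$pos; cig[i] <- r$cigar; sq[i] <- r$seq
  }
  data.table(qname = sprintf("%s:%s:%s%04d", gene_id, sample_id, tag, seq_len(n)),
             flag = 0L, rname = chrom, pos = pos, mapq = 60L,
             cigar = cig, seq = sq, nm = 0L)
}

# default sample design: tissue x condition x replicate
default_design <- function(cfg) {
  d <- data.table(expand.grid(replicate = seq_len(cfg$n_replicates),
                              condition = paste0("c", seq_len(cfg$n_conditions)),
                              tissue = paste0("T", seq_len(cfg$n_tissues)),
                              stringsAsFactors = FALSE))
  d[, sample_id := sprintf("%s_%s_r%d", tissue, condition, replicate)]
  data.table::setcolorder(d, c("sample_id", "tissue", "condition", "replicate"))
  d[]
}

#' Simulate junction reads at the planted inclusion levels
#'
#' For every planted micro-exon, tissue and replicate, `depth` reads are
#' drawn; each includes the micro-exon with the replicate-jittered true PSI
#' (truncated Normal(true_psi, replicate_noise_sd) on [0,1], Bernoulli per
#' read). Two alignment representations of the same fragments are emitted:
#' gap-aware genome alignments (detection input; inclusion fragments span the
#' whole micro-exon with both anchors >= `min_anchor`) and ungapped
#' alignments to the junction library (PSI input; each fragment is placed on
#' its dedicated junction — inclusion fragments alternate between the left
#' and right inclusion junction so both are covered evenly and each read
#' contributes exactly one junction observation).
#'
#' @param sim A `mex_sim`.
#' @param refs Junction library ([build_junction_library()] on the annotated
#'   micro-exons); built internally when NULL.
#' @param design Sample design (`sample_id`, `tissue`, `replicate`);
#'   defaults to the config's tissue x replicate grid.
#' @param depth Reads per micro-exon and sample (default `cfg$depth`).
#' @param what Which representations to generate ("genome", "library").
#' @param extra_left_reads Extra reads added to every micro-exon's *left*
#'   inclusion junction only (emulates an alternative 5' splice site
#'   inflating R_L; default 0).
#' @return list with `design`, `genome` (named list of SAM data.tables per
#'   sample), `library` (idem), and `refs`.
#' @export
simulate_junction_reads <- function(sim, refs = NULL, design = NULL,
                                    depth = NULL, what = c("genome", "library"),
                                    extra_left_reads = 0L) {
  cfg <- sim$cfg
  depth <- depth %||% cfg$depth
  design <- as.data.table(design %||% default_design(cfg))
  set.seed(derive_seed(cfg$seed, 3L))
  if (is.null(refs) && "library" %in% what) {
    mexs <- extract_annotated_microexons(sim$genes)
    refs <- build_junction_library(mexs, sim$genes)
  }
  genome_out <- library_out <- stats::setNames(
    vector("list", nrow(design)), design$sample_id)

  for (si in seq_len(nrow(design))) {
    g_rows <- list(); l_rows <- list()
    for (gi in seq_len(nrow(sim$truth))) {
      tr <- sim$truth[gi]
      psi_rep <- min(1, max(0, stats::rnorm(1, tr$true_psi, cfg$replicate_noise_sd)))
      n_inc <- stats::rbinom(1L, depth, psi_rep)
      n_exc <- depth - n_inc
      if ("genome" %in% what) {
        g_rows[[length(g_rows) + 1L]] <-
          sim_reads_for_mex(sim, tr$gene_id, n_inc, include = TRUE,
                            sample_id = design$sample_id[si])
        g_rows[[length(g_rows) + 1L]] <-
          sim_reads_for_mex(sim, tr$gene_id, n_exc, include = FALSE,
                            sample_id = design$sample_id[si])
      }
      if ("library" %in% what && tr$annotated) {
        rr <- refs[mex_id == tr$mex_id]
        if (nrow(rr))
          l_rows[[length(l_rows) + 1L]] <-
            library_reads(rr, n_inc, n_exc, cfg$read_length,
                          sample_id = design$sample_id[si],
                          extra_left = extra_left_reads)
      }
    }
    if ("genome" %in% what) genome_out[[si]] <- rbindlist(g_rows)
    if ("library" %in% what) library_out[[si]] <- rbindlist(l_rows)
  }
  list(design = design,
       genome = if ("genome" %in% what) genome_out else NULL,
       library = if ("library" %in% what) library_out else NULL,
       refs = refs)
}

# ungapped reads on the inclusion/exclusion references; inclusion reads
# alternate junctions, each spanning only its dedicated junction
library_reads <- function(ref, n_inc, n_exc, read_len, sample_id = "s1",
                          min_ov = 3L, extra_left = 0L) {
  up <- ref$up_len; mex <- ref$mex_len; down <- ref$down_len
  incl_len <- up + mex + down; excl_len <- up + down
  rows <- list()
  emit <- function(rname, pos, n, tag, ref_seq) {
    if (!length(pos)) return(NULL)
    data.table(qname = sprintf("%s:%s:%s%04d", ref$mex_id, sample_id, tag, seq_along(pos)),
               flag = 0L, rname = rname, pos = pos, mapq = 60L,
               cigar = sprintf("%dM", read_len),
               seq = substring(ref_seq, pos, pos + read_len - 1L), nm = 0L)
  }
  place_L <- function(n) {
    if (n <= 0L) return(integer(0))
    # right extension r in [min_ov, mex + min_ov - 1]: spans L junction only
    r_lo <- max(min_ov, read_len - up)
    r_hi <- min(mex + min_ov - 1L, incl_len - up, read_len - min_ov)
    if (r_lo > r_hi) r_hi <- min(read_len - min_ov, incl_len - up)
    r <- if (r_lo >= r_hi) rep(r_lo, n) else sample(r_lo:r_hi, n, replace = TRUE)
    up - (read_len - r) + 1L
  }
  place_R <- function(n) {
    if (n <= 0L) return(integer(0))
    # left part toward the mex <= mex + min_ov - 1: spans R junction only
    jr <- up + mex
    l_lo <- max(min_ov, read_len - (incl_len - jr))
    l_hi <- min(mex + min_ov - 1L, jr, read_len - min_ov)
    if (l_lo > l_hi) l_hi <- min(read_len - min_ov, jr)
    l <- if (l_lo >= l_hi) rep(l_lo, n) else sample(l_lo:l_hi, n, replace = TRUE)
    jr - l + 1L
  }
  place_S <- function(n) {
    if (n <= 0L) return(integer(0))
    l_lo <- max(min_ov, read_len - down)
    l_hi <- min(up, read_len - min_ov)
    l <- if (l_lo >= l_hi) rep(min(l_lo, up), n) else sample(l_lo:l_hi, n, replace = TRUE)
    up - l + 1L
  }
  nL <- ceiling(n_inc / 2); nR <- n_inc - nL
  rows$L <- emit(paste0(ref$mex_id, "|incl"), place_L(nL), nL, "L", ref$inclusion_seq)
  rows$R <- emit(paste0(ref$mex_id, "|incl"), place_R(nR), nR, "R", ref$inclusion_seq)
  if (extra_left > 0L)
    rows$X <- emit(paste0(ref$mex_id, "|incl"), place_L(extra_left), extra_left, "X",
                   ref$inclusion_seq)
  rows$S <- emit(paste0(ref$mex_id, "|excl"), place_S(n_exc), n_exc, "S", ref$exclusion_seq)
  rbindlist(rows)
}

#' Write simulated reads as per-sample SAM files
#' @param reads Result of [simulate_junction_reads()].
#' @param sim The `mex_sim` the reads came from (for genome @SQ lines).
#' @param dir Output directory.
#' @return list with named path vectors `genome` and `library`.
#' @export
write_sim_reads <- function(reads, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(genome = character(0), library = character(0))
  if (!is.null(reads$genome)) {
    rl <- stats::setNames(Biostrings::width(sim$genome), names(sim$genome))
    for (s in names(reads$genome)) {
      p <- file.path(dir, sprintf("genome_%s.sam", s))
      write_sam(reads$genome[[s]], p, rl)
      out$genome[s] <- p
    }
  }
  if (!is.null(reads$library) && !is.null(reads$refs)) {
    rl <- stats::setNames(
      c(nchar(reads$refs$inclusion_seq), nchar(reads$refs$exclusion_seq)),
      c(paste0(reads$refs$mex_id, "|incl"), paste0(reads$refs$mex_id, "|excl")))
    for (s in names(reads$library)) {
      p <- file.path(dir, sprintf("library_%s.sam", s))
      write_sam(reads$library[[s]], p, rl)
      out$library[s] <- p
    }
  }
  out
}

#' Simulate per-level homology hit tables with planted gene ages
#'
#' Every gene receives passing hits at its planted level and all younger
#' levels up to 12, plus decoy hits at older levels each failing exactly one
#' filter (e-value, identity or coverage, cycling); genes planted at PS13 get
#' decoys only. [assign_phylostratum()] on the filtered tables recovers every
#' planted level exactly.
#'
#' @param sim A `mex_sim` (uses `truth$ps_level`).
#' @return list with `hits` (HomologyHit table over all levels, unfiltered),
#'   `query_lengths` (named vector, protein lengths), `truth`
#'   (gene_id, ps_level).
#' @export
simulate_hit_tables <- function(sim) {
  cds_len <- sim$genes_true$cds[, .(cds_len = sum(end - start + 1L)),
                                by = transcript_id]
  cds_len <- merge(cds_len, sim$genes_true$transcripts[, .(transcript_id, gene_id)],
                   by = "transcript_id")
  qlen <- stats::setNames(as.integer(cds_len$cds_len / 3L), cds_len$gene_id)
  rows <- list()
  fail_modes <- c("evalue", "identity", "coverage")
  for (i in seq_len(nrow(sim$truth))) {
    g <- sim$truth$gene_id[i]; lv <- sim$truth$ps_level[i]; ql <- qlen[[g]]
    if (lv <= 12L) for (l in lv:12L)
      rows[[length(rows) + 1L]] <- data.table(
        query_id = g, db_level = l, evalue = 1e-20, identity = 0.6, coverage = 0.9)
    if (lv > 1L) for (l in seq_len(lv - 1L)) {
      mode <- fail_modes[(l - 1L) %% 3L + 1L]
      rows[[length(rows) + 1L]] <- data.table(
        query_id = g, db_level = l,
        evalue = if (mode == "evalue") 1e-3 else 1e-20,
        identity = if (mode == "identity") 0.25 else 0.6,
        coverage = if (mode == "coverage") 0.5 else 0.9)
    }
  }
  hits <- rbindlist(rows)
  list(hits = hits, query_lengths = qlen,
       truth = sim$truth[, .(gene_id, ps_level)])
}

#' Write simulated hit tables as per-level 12-column tabular files
#' @param tabs Result of [simulate_hit_tables()].
#' @param dir Output directory; writes `hits_level_NN.tsv` per level with any
#'   hits plus `query_lengths.tsv`.
#' @return Named vector of written per-level paths.
#' @export
write_hit_tables <- function(tabs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qlen <- tabs$query_lengths
  out <- character(0)
  for (l in sort(unique(tabs$hits$db_level))) {
    h <- tabs$hits[db_level == l]
    tab <- h[, .(V1 = query_id, V2 = sprintf("db%02d_subject", db_level),
                 V3 = identity * 100,
                 V4 = as.integer(round(coverage * qlen[query_id])),
                 V5 = 0L, V6 = 0L, V7 = 1L,
                 V8 = as.integer(round(coverage * qlen[query_id])),
                 V9 = 1L, V10 = as.integer(round(coverage * qlen[query_id])),
                 V11 = evalue, V12 = 100)]
    p <- file.path(dir, sprintf("hits_level_%02d.tsv", l))
    fwrite(tab, p, sep = "\t", col.names = FALSE, quote = FALSE)
    out[sprintf("%02d", l)] <- p
  }
  fwrite(data.table(gene_id = names(qlen), qlen = as.integer(qlen)),
         file.path(dir, "query_lengths.tsv"), sep = "\t", quote = FALSE)
  out
}

#' Simulate a collinear partner genome with planted conservation edits
#'
#' The partner is rebuilt from the reference blueprints: designated
#' micro-exons receive planted point substitutions (first `n_subs` positions,
#' base cycled A>C>G>T>A), designated genes have the micro-exon fused into
#' the downstream exon (the intervening intron is removed), and untouched
#' genes are copied verbatim. Partner gene/transcript ids carry a `_p`
#' suffix.
#'
#' @param sim A `mex_sim`.
#' @param edits data.table(gene_id, n_subs, merge); genes absent default to
#'   0 substitutions and no merge. NULL = identical partner (self-pair).
#' @return list with `partner` (a `mex_sim`-like object for the partner),
#'   `pairs` (collinear pair table gene_a/gene_b/block_id) and `expected`
#'   (gene_id, mex_id, expected verdict, expected n_substitutions).
#' @export
simulate_collinear_partner <- function(sim, edits = NULL) {
  edits <- as.data.table(edits %||% data.table(gene_id = character(),
                                               n_subs = integer(), merge = logical()))
  bp2 <- lapply(sim$blueprint, function(bp) {
    e <- edits[gene_id == bp$gene_id]
    n_subs <- if (nrow(e)) e$n_subs[1] %||% 0L else 0L
    do_merge <- if (nrow(e)) isTRUE(e$merge[1]) else FALSE
    mex_seq <- bp$exon_seqs[bp$mex_idx]
    if (!is.na(n_subs) && n_subs > 0L) {
      if (n_subs > nchar(mex_seq))
        stop_mex("gene '%s': %d substitutions exceed micro-exon length %d",
                 bp$gene_id, n_subs, nchar(mex_seq))
      ch <- strsplit(mex_seq, "")[[1]]
      cyc <- c(A = "C", C = "G", G = "T", T = "A")
      ch[seq_len(n_subs)] <- cyc[ch[seq_len(n_subs)]]
      mex_seq <- paste(ch, collapse = "")
      bp$exon_seqs[bp$mex_idx] <- mex_seq
    }
    if (do_merge) {
      k <- bp$mex_idx
      bp$exon_seqs[k] <- paste0(bp$exon_seqs[k], bp$exon_seqs[k + 1L])
      bp$exon_seqs <- bp$exon_seqs[-(k + 1L)]
      bp$intron_seqs <- bp$intron_seqs[-k]
      bp$mex_idx <- NA_integer_
    }
    bp$gene_id <- paste0(bp$gene_id, "_p")
    bp$tx_id <- paste0(bp$tx_id, "_p")
    bp$annotated <- TRUE
    bp$edit <- list(n_subs = n_subs, merge = do_merge)
    bp
  })
  # merged genes have no micro-exon; give assemble_sim a valid mex index
  bp_for_assembly <- lapply(bp2, function(bp) {
    if (is.na(bp$mex_idx)) bp$mex_idx <- 2L
    bp
  })
  partner <- assemble_sim(sim$cfg, bp_for_assembly)
  pairs <- data.table(gene_a = vapply(sim$blueprint, `[[`, "", "gene_id"),
                      gene_b = vapply(bp2, `[[`, "", "gene_id"),
                      block_id = "1")
  expected <- rbindlist(lapply(seq_along(bp2), function(i) {
    e <- bp2[[i]]$edit
    tr <- sim$truth[i]
    verdict <- if (e$merge) "not_conserved"
               else if (e$n_subs > 0L) "conserved_substituted" else "conserved_identical"
    data.table(gene_id = tr$gene_id, mex_id = tr$mex_id, verdict = verdict,
               n_substitutions = if (verdict == "conserved_substituted")
                 as.integer(e$n_subs) else if (verdict == "conserved_identical") 0L
               else NA_integer_,
               merged = e$merge)
  }))
  list(partner = partner, pairs = pairs, expected = expected)
}
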