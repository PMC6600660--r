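#' Default pipeline thresholds
#'
#' The defaults are the analysis' printed operating points: micro-exon
#' lengths 3-51 nt, 6-nt detection anchors, candidate support > 10 reads,
#' 100-nt junction flanks, 3-nt junction overhang, coverage floor 10, PSI
#' class bounds 0.1/0.9, replicate merge delta 0.10, homology filters
#' e <= 1e-5 / identity >= 0.3 / coverage >= 0.8. Every one is overridable
#' through the run config.
#' @export
default_thresholds <- function() {
  list(min_len = 3L, max_len = 51L, min_anchor = 6L, min_support = 10L,
       max_mismatches = 2L, flank = 100L, min_overhang = 3L, min_cov = 10L,
       cs_min = 0.9, as_min = 0.1, merge_delta = 0.10,
       max_e = 1e-5, min_ident = 0.3, min_cov_hom = 0.8)
}

validate_thresholds <- function(th) {
  dom <- list(min_len = c(3, 51), max_len = c(3, 51), min_anchor = c(1, 50),
              min_support = c(0, Inf), max_mismatches = c(0, 100),
              flank = c(1, 10000), min_overhang = c(1, 50), min_cov = c(0, Inf),
              cs_min = c(0, 1), as_min = c(0, 1), merge_delta = c(0, 1),
              max_e = c(0, Inf), min_ident = c(0, 1), min_cov_hom = c(0, 1))
  for (k in names(th)) {
    if (!k %in% names(dom)) next
    v <- th[[k]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < dom[[k]][1] || v > dom[[k]][2])
      stop_mex("run config: threshold '%s' = %s outside its domain [%s, %s]",
               k, format(v), dom[[k]][1], dom[[k]][2])
  }
  if (th$min_len > th$max_len) stop_mex("run config: min_len > max_len")
  if (th$as_min > th$cs_min) stop_mex("run config: as_min > cs_min")
  invisible(th)
}

#' Validate a pipeline run config
#'
#' @param config R list or path to a JSON config. Recognized fields: `out_dir`
#'   (required), `gff3`, `fasta`, `genome_sams` (named paths), `library_sams`
#'   (named paths), `design` (table or TSV path with sample_id, tissue,
#'   replicate and optionally condition), `hits_dir`, `query_lengths`,
#'   `partner_gff3`, `partner_fasta`, `pairs`, `domains_a`, `domains_b`,
#'   `seed`, and `thresholds` (partial override of [default_thresholds()]).
#' @return Normalized config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$out_dir)) stop_mex("run config: out_dir is required")
  th <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  validate_thresholds(th)
  config$thresholds <- th
  config$seed <- as.integer(config$seed %||% 1L)
  if (!is.null(config$design)) {
    d <- if (is.character(config$design)) fread(config$design) else as.data.table(config$design)
    if (!nrow(d)) stop_mex("run config: design table has no samples")
    need <- c("sample_id", "tissue", "replicate")
    if (!all(need %in% names(d)))
      stop_mex("run config: design table must have columns %s", paste(need, collapse = ", "))
    d[, unit_id := if ("condition" %in% names(d)) paste(tissue, condition, sep = ".")
                   else tissue]
    if (anyDuplicated(d[, .(unit_id, replicate)]))
      stop_mex("run config: replicate labels within a condition unit must be unique")
    config$design <- d
  }
  config
}

write_stage <- function(run_dir, name, writer) {
  path <- file.path(run_dir, name)
  writer(path)
  path
}

#' Run the full micro-exon pipeline
#'
#' Executes the stages in dependency order — annotation extraction, detection
#' from genome alignments, junction-library PSI quantification with replicate
#' merging and splice classification, tissue sets, phylostrata, conservation
#' — skipping stages whose inputs are not configured, and records a JSON
#' manifest (inputs, thresholds, seed, file checksums). Re-running an
#' identical config reproduces byte-identical outputs.
#'
#' @param config See [validate_run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_run_config(config)
  th <- cfg$thresholds
  run_dir <- cfg$out_dir
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(run_dir, "FAILED"))
  outputs <- character(0)
  stage <- "init"
  counts <- list()
  on_fail <- function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(run_dir, "FAILED"))
    stop_mex("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  }
  tryCatch({
    stage <- "annotation"
    if (is.null(cfg$gff3) || is.null(cfg$fasta))
      stop_mex("gff3 and fasta inputs are required")
    genes <- load_annotation(cfg$gff3, cfg$fasta)
    mexs <- extract_annotated_microexons(genes, th$min_len, th$max_len)
    outputs["microexons_tsv"] <- write_stage(run_dir, "01_microexons.tsv",
                                             function(p) write_microexon_tsv(mexs, p))
    outputs["microexons_bed"] <- write_stage(run_dir, "01_microexons.bed",
                                             function(p) write_microexon_bed(mexs, p))
    n_exons <- nrow(unique(genes$exons[, .(chrom, start, end)]))
    counts$annotation <- list(
      n_genes = nrow(genes$genes), n_exons = n_exons, n_microexons = nrow(mexs),
      n_internal = sum(mexs$positional_class == "internal"),
      microexon_exon_fraction = if (n_exons) nrow(mexs) / n_exons else NA_real_,
      gene_fraction = if (nrow(genes$genes))
        length(unique(mexs$gene_id)) / nrow(genes$genes) else NA_real_,
      in_frame_fraction = summarize_length_distribution(mexs)$in_frame_fraction)
    message(sprintf("[annotation] %d genes, %d exons, %d micro-exons",
                    counts$annotation$n_genes, n_exons, nrow(mexs)))

    if (!is.null(cfg$genome_sams)) {
      stage <- "detection"
      sams <- unlist(cfg$genome_sams)
      obs <- scan_alignments(sams, th$min_len, th$max_len, th$min_anchor,
                             th$max_mismatches)
      cand <- call_candidates(obs, th$min_support, genes, mexs)
      outputs["candidates"] <- write_stage(run_dir, "02_candidates.tsv",
                                           function(p) fwrite(cand, p, sep = "\t", quote = FALSE))
      counts$detection <- list(n_observations = nrow(obs), n_candidates = nrow(cand),
                               status_counts = as.list(table(cand$annotation_status)))
      message(sprintf("[detection] %d candidates from %d observation groups",
                      nrow(cand), nrow(obs)))
    }

    psi_merged <- NULL
    if (!is.null(cfg$library_sams) && !is.null(cfg$design)) {
      stage <- "psi"
      refs <- build_junction_library(mexs, genes, th$flank)
      outputs["junction_fasta"] <- write_stage(run_dir, "03_junction_library.fa",
                                               function(p) write_junction_fasta(refs, p))
      lsams <- unlist(cfg$library_sams)
      cnt <- count_junction_reads(lsams, refs, th$min_overhang, th$max_mismatches)
      outputs["junction_counts"] <- write_stage(run_dir, "03_junction_counts.tsv",
                                                function(p) fwrite(cnt, p, sep = "\t", quote = FALSE))
      psi <- compute_psi(cnt, th$min_cov)
      d <- cfg$design
      merged <- list()
      for (u in unique(d$unit_id)) {
        reps <- d[unit_id == u]
        ps <- lapply(reps$sample_id, function(s) psi[sample_id == s])
        m <- if (length(ps) >= 2L)
          merge_replicates(ps[[1]], ps[[2]], th$merge_delta, unit_id = u)
        else {
          x <- copy(ps[[1]])[, unit_id := u]
          x[, .(mex_id, psi, unit_id, splice_class)]
        }
        m[, tissue := reps$tissue[1]]
        merged[[u]] <- m
      }
      psi_merged <- rbindlist(merged, use.names = TRUE, fill = TRUE)
      psi_merged[, splice_class := classify_splicing(psi, th$cs_min, th$as_min)]
      outputs["psi_long"] <- write_stage(run_dir, "03_psi_merged.tsv",
                                         function(p) fwrite(psi_merged, p, sep = "\t", quote = FALSE))
      wide <- data.table::dcast(psi_merged, mex_id ~ unit_id, value.var = "psi")
      outputs["psi_matrix"] <- write_stage(run_dir, "03_psi_matrix.tsv",
                                           function(p) fwrite(wide, p, sep = "\t", quote = FALSE))
      counts$psi <- list(n_quantified = length(unique(psi_merged$mex_id)),
                         class_counts = as.list(table(psi_merged$splice_class)))
      message(sprintf("[psi] %d micro-exons quantified over %d units",
                      counts$psi$n_quantified, length(unique(psi_merged$unit_id))))

      stage <- "tissue_sets"
      sets <- tissue_expression_sets(psi_merged, th$as_min, 2L)
      outputs["tissue_overlap"] <- write_stage(run_dir, "04_tissue_overlap.tsv",
                                               function(p) fwrite(sets$overlap, p, sep = "\t", quote = FALSE))
      outputs["tissue_expressed"] <- write_stage(run_dir, "04_tissue_expressed.tsv",
                                                 function(p) fwrite(sets$expressed, p, sep = "\t", quote = FALSE))
      spec_dt <- rbindlist(lapply(names(sets$specific), function(tt)
        if (length(sets$specific[[tt]])) data.table(tissue = tt, mex_id = sets$specific[[tt]])
        else NULL))
      if (is.null(spec_dt) || !nrow(spec_dt)) spec_dt <- data.table(tissue = character(), mex_id = character())
      spec_dt <- merge(spec_dt, mexs[, .(mex_id, gene_id)], by = "mex_id", all.x = TRUE)
      outputs["tissue_specific"] <- write_stage(run_dir, "04_tissue_specific.tsv",
                                                function(p) fwrite(spec_dt, p, sep = "\t", quote = FALSE))
      counts$tissue_sets <- list(overlap = nrow(sets$overlap),
                                 n_specific = nrow(spec_dt))
    }

    if (!is.null(cfg$hits_dir) && !is.null(cfg$query_lengths)) {
      stage <- "phylostrata"
      qlen_tab <- fread(cfg$query_lengths)
      qlen <- stats::setNames(as.integer(qlen_tab[[2]]), qlen_tab[[1]])
      files <- sort(list.files(cfg$hits_dir, pattern = "^hits_level_\\d+\\.tsv$",
                               full.names = TRUE))
      hits <- rbindlist(lapply(files, function(f) {
        lv <- as.integer(sub("^hits_level_0*(\\d+)\\.tsv$", "\\1", basename(f)))
        read_homology_hits(f, lv, qlen)
      }))
      filt <- filter_hits(hits, th$max_e, th$min_ident, th$min_cov_hom)
      assign <- assign_phylostratum(sort(unique(mexs$gene_id)), filt)
      outputs["phylostrata"] <- write_stage(run_dir, "05_phylostrata.tsv",
                                            function(p) fwrite(assign, p, sep = "\t", quote = FALSE))
      counts$phylostrata <- list(class_counts = as.list(table(assign$age_class)))
      message(sprintf("[phylostrata] %d genes assigned", nrow(assign)))
    }

    if (!is.null(cfg$partner_gff3) && !is.null(cfg$partner_fasta) && !is.null(cfg$pairs)) {
      stage <- "conservation"
      genes_b <- load_annotation(cfg$partner_gff3, cfg$partner_fasta)
      pairs <- if (is.character(cfg$pairs)) read_collinear_pairs(cfg$pairs)
               else as.data.table(cfg$pairs)
      da <- if (!is.null(cfg$domains_a)) read_interproscan(cfg$domains_a) else NULL
      db <- if (!is.null(cfg$domains_b)) read_interproscan(cfg$domains_b) else NULL
      recs <- assess_conservation(mexs, pairs, genes, genes_b,
                                  species = cfg$partner_species %||% "partner",
                                  domains_a = da, domains_b = db)
      outputs["conservation"] <- write_stage(run_dir, "06_conservation.tsv",
                                             function(p) fwrite(recs, p, sep = "\t", quote = FALSE))
      summ <- conservation_summary(recs, stats::setNames(nrow(pairs),
                                                         cfg$partner_species %||% "partner"))
      outputs["conservation_summary"] <- write_stage(run_dir, "06_conservation_summary.tsv",
                                                     function(p) fwrite(summ$table, p, sep = "\t", quote = FALSE))
      counts$conservation <- list(n_records = nrow(recs),
                                  verdicts = as.list(table(recs$verdict)))
      message(sprintf("[conservation] %d records", nrow(recs)))
    }

    stage <- "manifest"
    jsonlite::write_json(counts, file.path(run_dir, "stage_counts.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs["stage_counts"] <- file.path(run_dir, "stage_counts.json")
    manifest <- list(
      package_version = as.character(utils::packageVersion("microexon")),
      seed = cfg$seed,
      thresholds = th,
      inputs = cfg[intersect(names(cfg), c("gff3", "fasta", "genome_sams",
                                           "library_sams", "hits_dir", "query_lengths",
                                           "partner_gff3", "partner_fasta", "pairs"))],
      outputs = as.list(stats::setNames(basename(outputs), names(outputs))),
      checksums = as.list(tools::md5sum(sort(unname(outputs))))
    )
    names(manifest$checksums) <- basename(names(manifest$checksums))
    jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report_summaries(run_dir)
    invisible(manifest)
  }, error = on_fail)
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs present under `run_dir` and writes a plain-text
#' report (`report.txt`) plus a machine-readable `summary.tsv`; sections
#' whose stage did not run are marked unavailable.
#'
#' @param run_dir Run directory from [run_pipeline()].
#' @return Invisibly, a list of summary sections.
#' @export
report_summaries <- function(run_dir) {
  lines <- c("micro-exon pipeline summary", "===========================")
  rows <- list()
  add <- function(metric, value) rows[[length(rows) + 1L]] <<- data.table(
    metric = metric, value = as.character(value))

  sc_path <- file.path(run_dir, "stage_counts.json")
  sc <- if (file.exists(sc_path)) jsonlite::read_json(sc_path, simplifyVector = TRUE) else list()

  if (!is.null(sc$annotation)) {
    a <- sc$annotation
    lines <- c(lines, "", "[annotation]",
               sprintf("  micro-exons: %d of %d exons (%.1f%%)", a$n_microexons,
                       a$n_exons, 100 * a$microexon_exon_fraction),
               sprintf("  genes with micro-exons: %.1f%%", 100 * a$gene_fraction),
               sprintf("  in-frame fraction: %.1f%%", 100 * a$in_frame_fraction))
    add("microexon_exon_fraction_pct", 100 * a$microexon_exon_fraction)
    add("gene_fraction_pct", 100 * a$gene_fraction)
    add("in_frame_fraction_pct", 100 * a$in_frame_fraction)
  } else lines <- c(lines, "", "[annotation] unavailable")

  if (!is.null(sc$detection)) {
    st <- sc$detection$status_counts
    lines <- c(lines, "", "[detection]",
               sprintf("  candidates: %d (annotated %s, novel-in-gene %s, intergenic %s)",
                       sc$detection$n_candidates, st$annotated %||% 0,
                       st$novel_in_gene %||% 0, st$novel_intergenic %||% 0))
    add("n_candidates", sc$detection$n_candidates)
    add("n_candidates_annotated", st$annotated %||% 0)
    add("n_candidates_novel_in_gene", st$novel_in_gene %||% 0)
  } else lines <- c(lines, "", "[detection] unavailable")

  psi_path <- file.path(run_dir, "03_psi_merged.tsv")
  if (file.exists(psi_path)) {
    pm <- fread(psi_path)
    cls <- pm[splice_class != "missing", .N, by = splice_class]
    tot <- sum(cls$N)
    n_of <- function(k) { v <- cls[splice_class == k]$N; if (length(v)) v else 0L }
    cs_pct <- 100 * n_of("CS") / max(tot, 1L)
    as_pct <- 100 * n_of("AS") / max(tot, 1L)
    lines <- c(lines, "", "[psi]",
               sprintf("  quantified micro-exon/unit pairs: %d (CS %.1f%%, AS %.1f%%)",
                       tot, cs_pct, as_pct))
    add("cs_pct", cs_pct); add("as_pct", as_pct)
  } else lines <- c(lines, "", "[psi] unavailable")

  ov_path <- file.path(run_dir, "04_tissue_overlap.tsv")
  if (file.exists(ov_path)) {
    ov <- fread(ov_path)
    lines <- c(lines, "", "[tissue sets]",
               sprintf("  %s: %d", ov$combination, ov$count))
  } else lines <- c(lines, "", "[tissue sets] unavailable")

  if (!is.null(sc$phylostrata)) {
    cc <- sc$phylostrata$class_counts
    tot <- sum(unlist(cc))
    lines <- c(lines, "", "[phylostrata]",
               sprintf("  old %.1f%%, young %.1f%%",
                       100 * (cc$old %||% 0) / tot, 100 * (cc$young %||% 0) / tot))
    add("old_pct", 100 * (cc$old %||% 0) / tot)
    add("young_pct", 100 * (cc$young %||% 0) / tot)
  } else lines <- c(lines, "", "[phylostrata] unavailable")

  cons_path <- file.path(run_dir, "06_conservation_summary.tsv")
  if (file.exists(cons_path)) {
    cs <- fread(cons_path)
    lines <- c(lines, "", "[conservation]",
               utils::capture.output(print(as.data.frame(cs), row.names = FALSE)))
  } else lines <- c(lines, "", "[conservation] unavailable")

  writeLines(lines, file.path(run_dir, "report.txt"))
  summary_dt <- if (length(rows)) rbindlist(rows) else
    data.table(metric = character(), value = character())
  fwrite(summary_dt, file.path(run_dir, "summary.tsv"), sep = "\t", quote = FALSE)
  invisible(list(lines = lines, summary = summary_dt))
}
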