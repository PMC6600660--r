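#' Default 13-level phylostratum taxonomy (rice-centric)
#'
#' Ordered names for PS1 (cellular organisms) through PS13 (the focal
#' species), usable as the default taxonomy config.
#' @export
default_phylostrata <- function() {
  c("Cellular organisms", "Eukaryota", "Viridiplantae",
    "Streptophyta/Streptophytina", "Embryophyta", "Tracheophyta/Euphyllophyta",
    "Spermatophyta", "Magnoliophyta/Mesangiospermae",
    "Liliopsida/Petrosaviidae/Commelinids/Poales", "Poaceae", "BOP clade",
    "Oryzoideae/Oryzeae/Oryza", "O. sativa")
}

#' Read one level's homology hits from 12-column tabular output
#'
#' The standard tabular dialect (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore) carries no query length, so
#' coverage is computed from a supplied query-length table as
#' `(qend - qstart + 1) / qlen` (aligned query span).
#'
#' @param path Tabular hit file for one database level.
#' @param level Integer taxonomy level (1-13) of the database searched.
#' @param query_lengths Named integer vector (query id -> protein length).
#' @return data.table of HomologyHit rows: `query_id`, `db_level`, `evalue`,
#'   `identity` (fraction), `coverage` (fraction).
#' @export
read_homology_hits <- function(path, level, query_lengths) {
  level <- as.integer(level)
  if (level < 1L || level > 13L) stop_mex("db level must be 1-13, got %d", level)
  cols <- c("query_id", "subject_id", "pident", "align_len", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  dt <- fread(path, header = FALSE, col.names = cols)
  if (!nrow(dt))
    return(data.table(query_id = character(), db_level = integer(),
                      evalue = numeric(), identity = numeric(), coverage = numeric()))
  missing_q <- setdiff(unique(dt$query_id), names(query_lengths))
  if (length(missing_q))
    stop_mex("query '%s' has no entry in query_lengths", missing_q[1])
  dt[, `:=`(db_level = level, identity = pident / 100,
            coverage = (qend - qstart + 1) / as.numeric(query_lengths[query_id]))]
  dt[, .(query_id, db_level, evalue, identity, coverage)]
}

#' Filter homology hits on e-value, identity and coverage
#'
#' All three comparisons are inclusive, as printed: e-value <= `max_e`,
#' identity >= `min_ident`, coverage >= `min_cov`.
#'
#' @param hits HomologyHit table ([read_homology_hits()]).
#' @param max_e,min_ident,min_cov Thresholds (defaults 1e-5, 0.3, 0.8).
#' @return The passing subset.
#' @export
filter_hits <- function(hits, max_e = 1e-5, min_ident = 0.3, min_cov = 0.8) {
  hits <- as.data.table(hits)
  bad <- hits[identity < 0 | identity > 1 | coverage < 0 | coverage > 1]
  if (nrow(bad))
    stop_mex("identity/coverage outside [0,1] for query '%s' at level %d (identity=%g, coverage=%g)",
             bad$query_id[1], bad$db_level[1], bad$identity[1], bad$coverage[1])
  hits[evalue <= max_e & identity >= min_ident & coverage >= min_cov]
}

#' Assign phylostrata (gene ages) from filtered hits
#'
#' A gene's phylostratum is the oldest (lowest-numbered) taxonomy level with
#' a qualifying hit; genes with no qualifying hit at any level default to
#' PS13 (species-specific). PS1-3 are "old", PS11-13 "young", the rest
#' "intermediate".
#'
#' @param gene_ids Character vector: the gene universe to assign (genes
#'   absent from `filtered` get PS13).
#' @param filtered Filtered HomologyHit table ([filter_hits()]).
#' @return data.table `gene_id`, `ps`, `age_class`.
#' @details A hit at level <= 12 with 100% identity and full coverage is
#'   usually a self-hit the database construction should have excluded; a
#'   warning is raised when one is seen.
#' @export
assign_phylostratum <- function(gene_ids, filtered) {
  filtered <- as.data.table(filtered)
  if (nrow(filtered)) {
    selfish <- filtered[db_level <= 12L & identity >= 1 & coverage >= 1]
    if (nrow(selfish))
      warn_mex("possible self-hit(s): e.g. query '%s' at level %d with 100%% identity and full coverage",
               selfish$query_id[1], selfish$db_level[1])
  }
  ps_map <- if (nrow(filtered))
    filtered[, .(ps = min(db_level)), by = .(gene_id = query_id)]
  else data.table(gene_id = character(), ps = integer())
  out <- data.table(gene_id = gene_ids)
  out <- merge(out, ps_map, by = "gene_id", all.x = TRUE, sort = TRUE)
  out[is.na(ps), ps := 13L]
  out[, age_class := ifelse(ps <= 3L, "old", ifelse(ps >= 11L, "young", "intermediate"))]
  setorder(out, gene_id)
  out[]
}

#' Summaries of gene features by evolutionary age class
#'
#' @param assignments From [assign_phylostratum()].
#' @param cds_lengths Named numeric vector of coding lengths per gene (or a
#'   two-column table gene_id/cds_len); genes missing from it are dropped
#'   with a warning.
#' @param mexs Optional micro-exon table (adds micro-exon length summaries).
#' @param expression Optional long table `gene_id`, `tissue`, `fpkm` (adds
#'   per-tissue expression summaries).
#' @return list of data.tables: `class_fractions`, `cds_length`,
#'   `microexon_length` (when `mexs` given), `expression` (when given);
#'   distribution summaries report median and quartiles.
#' @export
age_summaries <- function(assignments, cds_lengths, mexs = NULL, expression = NULL) {
  assignments <- as.data.table(assignments)
  if (is.data.frame(cds_lengths)) {
    v <- cds_lengths[[2]]; names(v) <- cds_lengths[[1]]; cds_lengths <- v
  }
  known <- assignments$gene_id %in% names(cds_lengths)
  if (any(!known)) {
    warn_mex("%d gene(s) in assignments missing from annotation/CDS lengths; excluded",
             sum(!known))
    assignments <- assignments[known]
  }
  q <- function(x) as.list(stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE))
  frac <- assignments[, .(n = .N), by = age_class][, `:=`(fraction = n / sum(n))]
  setorder(frac, age_class)
  cdl <- assignments[, {
    x <- as.numeric(cds_lengths[gene_id])
    c(list(n = .N), stats::setNames(q(x), c("q25", "median", "q75")))
  }, by = age_class]
  out <- list(class_fractions = frac[], cds_length = cdl[])
  if (!is.null(mexs) && nrow(mexs)) {
    ml <- merge(mexs[, .(gene_id, length_nt)], assignments, by = "gene_id")
    if (nrow(ml))
      out$microexon_length <- ml[, c(list(n = .N),
                                     stats::setNames(q(as.numeric(length_nt)),
                                                     c("q25", "median", "q75"))),
                                 by = age_class][]
  }
  if (!is.null(expression) && nrow(expression)) {
    ee <- merge(as.data.table(expression), assignments, by = "gene_id")
    if (nrow(ee))
      out$expression <- ee[, c(list(n = .N),
                               stats::setNames(q(as.numeric(fpkm)),
                                               c("q25", "median", "q75"))),
                           by = .(age_class, tissue)][]
  }
  out
}
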