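#' @importFrom data.table data.table as.data.table setkey setorder rbindlist fread fwrite := .N .SD setnames copy
#' @importFrom methods is
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "..tissues", "chrom", "start", "end", "strand", "gene_id", "transcript_id",
  "exon_rank", "length_nt", "positional_class", "coding_status", "frame_class",
  "mex_id", "sample_id", "n_reads", "anchor_min", "total_support", "R_L", "R_R",
  "R_skipped", "R_tot", "psi", "splice_class", "unit_id", "tissue", "db_level",
  "evalue", "identity", "coverage", "ps", "age_class", "query_id", "phase",
  "n_exons", "cds_len", "expressed", "verdict", "species", "n_substitutions",
  "group_id", "annotation_status", "exon_len", "type", "ID", "bad", "tx_strand",
  "tx_order", "fpkm", "pident", "qstart", "qend", "V1", "V5", "V7", "V8",
  "sp_start", "sp_end", "spliced_len", "up_len", "down_len", "mex_len",
  "l_off", "r_off", "skip_off", "inclusion_seq", "exclusion_seq",
  "aln_start", "aln_end", "mex", "role", "i.N", "rname", "nm", "cigar",
  "anchor", "min_sample_support", "conserved", "gene_a", "gene_b",
  "domain_consistent", "overlap", "a_pos", "b_pos", "psi_a", "psi_b",
  "combination", "condition", "replicate", "near_annotated", "qname", "flag",
  "mapq"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mex <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_mex <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic child seed derived from a user seed; kept < 2^31
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 1103L + as.integer(salt) * 12289L) %% 2147483583L + 1L
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @keywords internal
check_fraction <- function(x, name) {
  if (any(!is.na(x) & (x < 0 | x > 1)))
    stop_mex("%s must lie in [0,1]; offending value(s): %s", name,
             paste(utils::head(x[!is.na(x) & (x < 0 | x > 1)], 3), collapse = ", "))
  invisible(x)
}
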