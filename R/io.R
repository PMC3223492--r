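#' Export a test set as FASTA + TSV + YAML
#'
#' Writes `sequences.fasta` (record IDs `pair<k>_s1` / `pair<k>_s2`),
#' `reference.tsv` (columns `pair_id`, `i`, `j`; 0-based full-sequence
#' coordinates of the gold-standard match columns), `cores.tsv` (columns
#' `pair_id`, `seq`, `start`, `end`; 0-based half-open core ranges) and
#' `config.yaml` echoing the generation parameters.
#'
#' @param ts A `test_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_test_set <- function(ts, dir) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA export")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- unlist(lapply(seq_along(ts$pairs), function(k)
    c(ts$pairs[[k]]$s1, ts$pairs[[k]]$s2)))
  names(seqs) <- paste0("pair", rep(seq_along(ts$pairs), each = 2),
                        c("_s1", "_s2"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                              file.path(dir, "sequences.fasta"))
  ref <- do.call(rbind, lapply(seq_along(ts$pairs), function(k) {
    r <- ts$pairs[[k]]$reference
    if (nrow(r) == 0L) return(NULL)
    data.frame(pair_id = k, i = r[, "i"] - 1L, j = r[, "j"] - 1L)
  }))
  write.table(ref, file.path(dir, "reference.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cores <- do.call(rbind, lapply(seq_along(ts$pairs), function(k) {
    p <- ts$pairs[[k]]
    data.frame(pair_id = k, seq = 1:2,
               start = c(p$core1[["start"]], p$core2[["start"]]) - 1L,
               end = c(p$core1[["end"]], p$core2[["end"]]))
  }))
  write.table(cores, file.path(dir, "cores.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(
    pam = ts$params$pam, p_del = ts$params$p_del,
    zipf_exponent = ts$params$zipf_exponent,
    max_indel_len = ts$params$max_indel_len,
    ancestor_length = ts$params$ancestor_length,
    r = ts$spec$r, c = ts$spec$c, n_pairs = ts$n_pairs,
    seed = ts$seed, scheme = ts$scheme), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a two-record FASTA file as a sequence pair
#'
#' @param path FASTA file with exactly two records.
#' @return Named character vector of length 2.
#' @export
read_fasta_pair <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("Biostrings is required for FASTA input")
  x <- Biostrings::readAAStringSet(path)
  if (length(x) != 2L) stop("expected exactly 2 FASTA records, got ", length(x))
  stats::setNames(as.character(x), names(x))
}

#' Export an alignment as aligned FASTA and a TSV column list
#'
#' @param a A `pairwise_alignment`.
#' @param fasta,tsv Output paths (either may be `NULL` to skip).
#' @param ids Record IDs for the FASTA output.
#' @return `a`, invisibly.
#' @export
write_alignment <- function(a, fasta = NULL, tsv = NULL,
                            ids = c("s1", "s2")) {
  if (!is.null(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stop("Biostrings is required for FASTA export")
    s <- alignment_strings(a)
    names(s) <- ids
    Biostrings::writeXStringSet(Biostrings::AAStringSet(s), fasta)
  }
  if (!is.null(tsv)) {
    cols <- data.frame(i = a$columns[, 1L] - 1L, j = a$columns[, 2L] - 1L)
    write.table(cols, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(a)
}
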