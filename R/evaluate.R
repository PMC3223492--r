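#' Alignment quality from raw column counts
#'
#' Given the number of gold-standard match columns `G`, assessed algorithmic
#' match columns `A` and common match columns `I`, the quality measures are
#' `accuracy = I / G` (how much of the true alignment was recovered) and
#' `confidence = I / A` (how much of the reported alignment is correct).
#'
#' @param G,A,I Non-negative counts with `I <= min(G, A)`.
#' @return An object of class `quality_result` with fields `G`, `A`, `I`,
#'   `accuracy` and `confidence`; a ratio with a zero denominator is `NA`.
#' @export
quality_from_counts <- function(G, A, I) {
  stopifnot(G >= 0, A >= 0, I >= 0, I <= min(G, A))
  structure(list(G = G, A = A, I = I,
                 accuracy = if (G > 0) I / G else NA_real_,
                 confidence = if (A > 0) I / A else NA_real_),
            class = "quality_result")
}

#' @export
print.quality_result <- function(x, ...) {
  cat(sprintf("G = %d, A = %d, I = %d; accuracy = %s, confidence = %s\n",
              x$G, x$A, x$I,
              format(x$accuracy, digits = 4), format(x$confidence, digits = 4)))
  invisible(x)
}

#' Quality of an algorithmic alignment against the gold standard
#'
#' Only columns touching a homologous region are assessed: `A` counts the
#' algorithmic match columns (no gap on either side) whose first position
#' lies in core 1 or whose second position lies in core 2; console-to-console
#' matches are ignored because console positions are unaligned in the
#' reference.  `I` counts algorithmic match columns that occur in the
#' reference, and `G` is the reference size.
#'
#' @param algorithmic A `pairwise_alignment` of `pair$s1` vs `pair$s2`.
#' @param pair A `test_pair` carrying the gold-standard `reference`.
#' @return A [quality_from_counts()] object.
#' @export
evaluate_pair <- function(algorithmic, pair) {
  cols <- algorithmic$columns
  n1 <- nchar(pair$s1)
  n2 <- nchar(pair$s2)
  if (nrow(cols) > 0L) {
    if (max(cols[, 1L], 0, na.rm = TRUE) > n1 ||
        max(cols[, 2L], 0, na.rm = TRUE) > n2)
      stop("alignment coordinates exceed sequence lengths")
  }
  m <- !is.na(cols[, 1L]) & !is.na(cols[, 2L])
  i <- cols[m, 1L]
  j <- cols[m, 2L]
  in_core1 <- i >= pair$core1[["start"]] & i <= pair$core1[["end"]]
  in_core2 <- j >= pair$core2[["start"]] & j <= pair$core2[["end"]]
  assessed <- in_core1 | in_core2
  key <- function(ii, jj) ii * (n2 + 1) + jj
  common <- sum(key(i, j) %in% key(pair$reference[, "i"], pair$reference[, "j"]))
  quality_from_counts(G = nrow(pair$reference), A = sum(assessed), I = common)
}

#' Aggregate per-pair quality into mean accuracy and confidence
#'
#' Unweighted per-pair means, reported in percent.  Pairs whose algorithmic
#' alignment vanished (`A = 0`, e.g. an empty local alignment) contribute
#' zero accuracy and zero confidence: a vanished alignment restores nothing.
#' Pairs with an empty reference (`G = 0`) carry no quality information and
#' are dropped.
#'
#' @param results List of [quality_from_counts()] objects.
#' @return Named numeric vector `c(accuracy, confidence)` in percent.
#' @export
aggregate_quality <- function(results) {
  if (length(results) == 0L) stop("'results' must be non-empty")
  vals <- vapply(results, function(q) {
    if (q$G == 0) return(c(NA_real_, NA_real_))
    if (q$A == 0) return(c(0, 0))
    c(q$accuracy, q$confidence)
  }, numeric(2))
  c(accuracy = 100 * mean(vals[1, ], na.rm = TRUE),
    confidence = 100 * mean(vals[2, ], na.rm = TRUE))
}

#' The gold-standard reference as a full pairwise alignment
#'
#' Expands the reference match-column list into alignment columns covering
#' both complete sequences: consoles and unmatched core positions appear as
#' gap columns (sequence-1 positions first between consecutive matches).
#' Mainly used for validation and for scoring reference alignments.
#'
#' @param pair A `test_pair`.
#' @param cores_only If `TRUE`, restrict to core positions (used when
#'   scoring the reference alignment of cores).
#' @return A `pairwise_alignment` whose match columns are exactly the
#'   reference.
#' @export
reference_alignment <- function(pair, cores_only = FALSE) {
  ref <- pair$reference
  lo1 <- if (cores_only) pair$core1[["start"]] else 1L
  hi1 <- if (cores_only) pair$core1[["end"]] else nchar(pair$s1)
  lo2 <- if (cores_only) pair$core2[["start"]] else 1L
  hi2 <- if (cores_only) pair$core2[["end"]] else nchar(pair$s2)
  ci <- integer(0)
  cj <- integer(0)
  p1 <- lo1
  p2 <- lo2
  emit_to <- function(i_stop, j_stop) {
    while (p1 < i_stop) { ci <<- c(ci, p1); cj <<- c(cj, NA_integer_); p1 <<- p1 + 1L }
    while (p2 < j_stop) { ci <<- c(ci, NA_integer_); cj <<- c(cj, p2); p2 <<- p2 + 1L }
  }
  for (k in seq_len(nrow(ref))) {
    emit_to(ref[k, "i"], ref[k, "j"])
    ci <- c(ci, p1)
    cj <- c(cj, p2)
    p1 <- p1 + 1L
    p2 <- p2 + 1L
  }
  emit_to(hi1 + 1L, hi2 + 1L)
  if (cores_only) {
    s1 <- substr(pair$s1, lo1, hi1)
    s2 <- substr(pair$s2, lo2, hi2)
    ci <- ci - lo1 + 1L
    cj <- cj - lo2 + 1L
  } else {
    s1 <- pair$s1
    s2 <- pair$s2
  }
  new_alignment(cbind(i = ci, j = cj), NA_real_, "reference", s1, s2)
}
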