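#' Affine gap penalty
#'
#' A gap of length `g` costs `gop + gep * g`: opening charges `gop + gep` for
#' the first gapped position, each further position adds `gep`.  This
#' convention (rather than `gop + gep * (g - 1)`) is used consistently by the
#' aligners, the alignment re-scorer and the slope-zone density model, and
#' end gaps in global mode are penalized in full.
#'
#' @param gop Gap-open penalty (>= 0).
#' @param gep Gap-extension penalty (>= 0).
#' @return An object of class `gap_penalty`.
#' @export
gap_penalty <- function(gop, gep) {
  stopifnot(length(gop) == 1L, gop >= 0, length(gep) == 1L, gep >= 0)
  structure(list(gop = gop, gep = gep), class = "gap_penalty")
}

gap_cost <- function(gap, g) ifelse(g > 0, gap$gop + gap$gep * g, 0)

new_alignment <- function(columns, score, mode, s1, s2) {
  structure(list(columns = columns, score = score, mode = mode,
                 s1 = s1, s2 = s2), class = "pairwise_alignment")
}

run_gotoh <- function(s1, s2, matrix, gap, local) {
  c1 <- aa_encode(s1)
  c2 <- aa_encode(s2)
  if (length(c1) == 0L || length(c2) == 0L)
    stop("sequences must be non-empty")
  res <- .gotoh_align(c1 - 1L, c2 - 1L, unclass(matrix), gap$gop, gap$gep, local)
  cols <- cbind(i = res$i, j = res$j)
  new_alignment(cols, res$score, if (local) "local" else "global", s1, s2)
}

#' Optimal global (Needleman-Wunsch/Gotoh) affine-gap alignment
#'
#' Three-state dynamic programming over match / gap-in-sequence-2 /
#' gap-in-sequence-1 states; the score is the maximum over all global
#' alignments of summed substitution weights minus summed gap costs, with
#' end gaps penalized.  Ties are broken deterministically (match preferred
#' over a gap in sequence 2, preferred over a gap in sequence 1).
#'
#' @param s1,s2 Residue sequences (character strings or vectors).
#' @param matrix 20 x 20 substitution weight matrix (default the package's
#'   real-valued PAM250).
#' @param gap A [gap_penalty()]; the default 14/2 pairs with PAM250.
#' @return An object of class `pairwise_alignment` with elements `columns`
#'   (two-column matrix of 1-based positions, `NA` marking a gap), `score`
#'   and `mode`.
#' @export
align_global <- function(s1, s2, matrix = scoring_matrix("PAM250"),
                         gap = gap_penalty(14, 2)) {
  run_gotoh(s1, s2, matrix, gap, local = FALSE)
}

#' Optimal local (Smith-Waterman/Gotoh) affine-gap alignment
#'
#' Maximizes the global score over all pairs of fragments, floored at zero;
#' an empty alignment (score 0) is returned when no fragment pair scores
#' positively.  Among co-optimal fragments the one with the smallest end
#' coordinates wins.
#'
#' @inheritParams align_global
#' @param gap A [gap_penalty()]; the default 10/0.5 pairs with Gonnet250.
#' @return A `pairwise_alignment` (mode `"local"`, `score >= 0`).
#' @export
align_local <- function(s1, s2, matrix = scoring_matrix("Gonnet250"),
                        gap = gap_penalty(10, 0.5)) {
  run_gotoh(s1, s2, matrix, gap, local = TRUE)
}

#' Re-score an alignment from its columns
#'
#' Sums substitution weights over match columns and subtracts
#' `gop + gep * length` for every maximal gap run, independently of how the
#' alignment was produced.  Useful for validating aligner output and for
#' scoring gold-standard reference alignments.
#'
#' @param a A `pairwise_alignment` (or any list with a `columns` matrix and
#'   the two sequences).
#' @param matrix Substitution matrix.
#' @param gap A [gap_penalty()].
#' @return The alignment score (0 for an empty alignment).
#' @export
score_alignment <- function(a, matrix = scoring_matrix("PAM250"),
                            gap = gap_penalty(14, 2)) {
  cols <- a$columns
  if (is.null(cols) || nrow(cols) == 0L) return(0)
  gi <- is.na(cols[, 1L])
  gj <- is.na(cols[, 2L])
  if (any(gi & gj)) stop("malformed alignment: (gap, gap) column")
  c1 <- aa_encode(a$s1)
  c2 <- aa_encode(a$s2)
  if (any(cols[!gi, 1L] > length(c1)) || any(cols[!gj, 2L] > length(c2)))
    stop("malformed alignment: position out of range")
  m <- !gi & !gj
  sub_score <- sum(matrix[cbind(c1[cols[m, 1L]], c2[cols[m, 2L]])])
  run_lengths <- function(isgap) {
    r <- rle(isgap)
    r$lengths[r$values]
  }
  gap_score <- sum(gap_cost(gap, run_lengths(gi))) +
    sum(gap_cost(gap, run_lengths(gj)))
  sub_score - gap_score
}

#' Gapped sequence strings of an alignment
#'
#' @param a A `pairwise_alignment`.
#' @param gap_char Character used for gaps.
#' @return Character vector of the two aligned strings.
#' @export
alignment_strings <- function(a, gap_char = "-") {
  cols <- a$columns
  r1 <- strsplit(a$s1, "")[[1]]
  r2 <- strsplit(a$s2, "")[[1]]
  x1 <- ifelse(is.na(cols[, 1L]), gap_char, r1[cols[, 1L]])
  x2 <- ifelse(is.na(cols[, 2L]), gap_char, r2[cols[, 2L]])
  c(paste(x1, collapse = ""), paste(x2, collapse = ""))
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(sprintf("%s alignment, score %.2f, %d columns\n",
              x$mode, x$score, nrow(x$columns)))
  if (nrow(x$columns) > 0L) {
    s <- alignment_strings(x)
    n <- nchar(s[1])
    for (start in seq(1L, n, by = width)) {
      end <- min(start + width - 1L, n)
      cat(substr(s[1], start, end), "\n")
      cat(substr(s[2], start, end), "\n\n")
    }
  }
  invisible(x)
}
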