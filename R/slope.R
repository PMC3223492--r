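#' Parameters of the alignment-density model
#'
#' Mean quantities entering the analytic prediction of where global
#' alignment collapses: mean core length `l_ker`; mean density (score per
#' residue) of the gold-standard core alignment `d_ker`; total console length
#' per sequence `l_con`; mean density of aligning two independent random
#' sequences at console scale `d_con`; mean density of the optimal global
#' alignment of two random sequences of length `l_ker + l_con`, `d_rand`;
#' and the gap penalties.
#'
#' @param l_ker,l_con Lengths in residues (`l_ker > 0`, `l_con >= 0`).
#' @param d_ker,d_con,d_rand Densities in score units per residue.
#' @param gop,gep Gap penalties (defaults 14/2, the global-aligner setting).
#' @return An object of class `density_params`.
#' @export
density_params <- function(l_ker, d_ker, l_con, d_con, d_rand,
                           gop = 14, gep = 2) {
  stopifnot(l_ker > 0, l_con >= 0)
  structure(list(l_ker = l_ker, d_ker = d_ker, l_con = l_con,
                 d_con = d_con, d_rand = d_rand, gop = gop, gep = gep),
            class = "density_params")
}

#' Expected global score of a reference alignment at console asymmetry c
#'
#' The model decomposes the expected global score into the core contribution
#' `l_ker * d_ker`, the overlap of opposite consoles `l_con * d_con * (1 - c)`
#' (shrinking as the consoles shift apart), the gap extension cost of the
#' non-overlapping console parts `2 * gep * l_con * c`, and two gap openings:
#' `score = l_ker*d_ker + l_con*d_con*(1-c) - 2*gep*l_con*c - 2*gop`.
#'
#' @param c Console asymmetry in `[0, 1]` (vectorized).
#' @param p A [density_params()] object.
#' @return Expected score (same length as `c`).
#' @export
score_glob <- function(c, p) {
  if (any(c < 0 | c > 1)) stop("'c' must lie in [0, 1]")
  p$l_ker * p$d_ker + p$l_con * p$d_con * (1 - c) -
    2 * p$gep * p$l_con * c - 2 * p$gop
}

#' Expected global alignment density at console asymmetry c
#'
#' `score_glob(c) / (l_ker + l_con)`, an affine decreasing function of `c`
#' whenever `d_con + 2 * gep > 0`.
#'
#' @inheritParams score_glob
#' @return Expected density (score per residue).
#' @export
d_glob <- function(c, p) score_glob(c, p) / (p$l_ker + p$l_con)

#' Critical console asymmetry where global alignment collapses
#'
#' Solves the linear equation `d_glob(c) = d_rand` in closed form:
#' the asymmetry at which the expected reference-alignment density sinks to
#' the density of aligning pure random sequences, beyond which the global
#' algorithm cannot distinguish the true alignment from noise.  Returns `NA`
#' (reported as "none") when the root falls outside `[0, 1]`.
#'
#' @param p A [density_params()] object.
#' @return The critical asymmetry `c*` in `[0, 1]`, or `NA` if none.
#' @export
critical_asymmetry <- function(p) {
  denom <- p$l_con * (p$d_con + 2 * p$gep)
  if (abs(denom) < .Machine$double.eps * 100)
    stop("degenerate density model: l_con * (d_con + 2*gep) is zero")
  c_star <- (p$l_ker * p$d_ker + p$l_con * p$d_con - 2 * p$gop -
               p$d_rand * (p$l_ker + p$l_con)) / denom
  if (c_star < 0 || c_star > 1) NA_real_ else c_star
}

#' Monte-Carlo density of global alignments of random sequence pairs
#'
#' For each length, draws `n_reps` pairs of i.i.d. background sequences,
#' aligns them globally and averages score/length.  Reproduces the
#' density-versus-length curve whose short-length limit approaches the mean
#' random substitution score.
#'
#' @param lengths Vector of positive sequence lengths.
#' @param matrix,gap Aligner parameterization (defaults PAM250, 14/2).
#' @param n_reps Number of pairs per length.
#' @param background Residue frequency vector.
#' @return A data frame with columns `length` and `density`.
#' @export
estimate_density_curve <- function(lengths, matrix = scoring_matrix("PAM250"),
                                   gap = gap_penalty(14, 2), n_reps = 1000,
                                   background = mutation_model()$background) {
  if (length(lengths) == 0L) stop("'lengths' must be non-empty")
  stopifnot(all(lengths >= 1), n_reps >= 1)
  dens <- vapply(lengths, function(L) {
    mean(vapply(seq_len(n_reps), function(k) {
      s1 <- sample.int(20L, L, replace = TRUE, prob = background) - 1L
      s2 <- sample.int(20L, L, replace = TRUE, prob = background) - 1L
      .gotoh_align(s1, s2, unclass(matrix), gap$gop, gap$gep, FALSE)$score / L
    }, numeric(1)))
  }, numeric(1))
  data.frame(length = lengths, density = dens)
}

#' Mean gold-standard core alignment density of a test set
#'
#' Scores the reference alignment of the cores of every pair and divides by
#' the mean core length of the pair; returns the set average.  With
#' `gap_costs = TRUE` every unmatched run is charged `gop + gep * g` on top
#' of the substitution weights of the match columns; with
#' `gap_costs = FALSE` only the substitution weights are summed, which
#' measures the recoverable homology signal per core residue (the quantity
#' entering the collapse prediction — charging the indel costs here would
#' double-count them against the gap terms of the score decomposition).
#'
#' @param ts A `test_set`.
#' @param matrix,gap Scoring parameterization.
#' @param gap_costs Charge affine gap costs for unmatched core positions.
#' @return Mean core alignment density (score per residue).
#' @export
estimate_core_density <- function(ts, matrix = scoring_matrix("PAM250"),
                                  gap = gap_penalty(14, 2), gap_costs = TRUE) {
  if (!inherits(ts, "test_set") || ts$n_pairs == 0L)
    stop("'ts' must be a non-empty test_set")
  if (!gap_costs) gap <- gap_penalty(0, 0)
  mean(vapply(ts$pairs, function(p) {
    a <- reference_alignment(p, cores_only = TRUE)
    score_alignment(a, matrix, gap) / mean(c(length(p$k1), length(p$k2)))
  }, numeric(1)))
}

#' Locate the empirical slope zone of an accuracy-versus-asymmetry curve
#'
#' The slope zone is the narrow range of console asymmetry over which global
#' alignment accuracy collapses.  It is localized as the c-grid interval
#' with the steepest accuracy decrease; the zone reported is the interval
#' midpoint plus/minus `half_width` (default 0.1, i.e. the ~20%-wide band
#' seen empirically).
#'
#' @param c_values Increasing grid of asymmetry values.
#' @param accuracy Accuracy (in percent or fraction) at each grid point.
#' @param half_width Half-width of the reported zone.
#' @return List with `midpoint`, `lower` and `upper`.
#' @export
locate_slope_zone <- function(c_values, accuracy, half_width = 0.1) {
  stopifnot(length(c_values) == length(accuracy), length(c_values) >= 2)
  drop_ <- -diff(accuracy)
  k <- which.max(drop_)
  mid <- (c_values[k] + c_values[k + 1L]) / 2
  list(midpoint = mid, lower = mid - half_width, upper = mid + half_width)
}

#' Estimate the full density model from a simulated test set
#'
#' Convenience fitter for [critical_asymmetry()]: estimates `l_ker` and
#' `d_ker` from the set's gold-standard core alignments (substitution
#' weights only — see [estimate_core_density()] for why indel costs are not
#' charged here), takes `l_con = round(r * ancestor_length)`, and estimates
#' `d_con` and `d_rand` by Monte-Carlo global alignment of random pairs at
#' console scale and at full sequence scale `l_ker + l_con` respectively.
#'
#' @param ts A diverging-scheme `test_set`.
#' @param matrix,gap Global-aligner parameterization entering the model.
#' @param n_reps Monte-Carlo replicates for the random densities.
#' @return A [density_params()] object.
#' @export
fit_density_params <- function(ts, matrix = scoring_matrix("PAM250"),
                               gap = gap_penalty(14, 2), n_reps = 500) {
  l_ker <- mean(vapply(ts$pairs, function(p)
    mean(c(length(p$k1), length(p$k2))), numeric(1)))
  d_ker <- estimate_core_density(ts, matrix, gap, gap_costs = FALSE)
  l_con <- round(ts$spec$r * ts$params$ancestor_length)
  d_con <- if (l_con > 0)
    estimate_density_curve(l_con, matrix, gap, n_reps)$density
  else 0
  d_rand <- estimate_density_curve(round(l_ker + l_con), matrix, gap,
                                   n_reps)$density
  density_params(l_ker = l_ker, d_ker = d_ker, l_con = l_con,
                 d_con = d_con, d_rand = d_rand, gop = gap$gop, gep = gap$gep)
}
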