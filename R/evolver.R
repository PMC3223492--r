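#' Evolution parameters for core generation
#'
#' Bundles the knobs of the sequence-evolution model: the per-branch
#' evolutionary distance in PAM units, the indel model (deletion probability,
#' Zipfian length law with truncation) and the ancestor length.
#'
#' Defaults follow the study design this package reproduces: deletions are
#' drawn with probability 0.55 (which balances total inserted and deleted
#' residues under the placement rules), indel lengths follow a truncated
#' Zipf law, and ancestors are 200 residues long.
#'
#' @param pam Positive integer, evolutionary distance per branch (number of
#'   PAM1 substitution cycles).
#' @param p_del Probability that a sampled indel is a deletion (strictly
#'   between 0 and 1).
#' @param zipf_exponent Exponent of the Zipfian indel-length distribution
#'   (must exceed 1).
#' @param max_indel_len Truncation of the indel-length support.
#' @param ancestor_length Length of the Bernoulli ancestor sequence.
#' @param indel_rate Optional override of the per-position indel probability
#'   (normally derived from `pam` via [indel_probability()]); `0` disables
#'   indels entirely.  Intended for validation and degenerate runs.
#' @param cycles Optional override of the number of point-mutation cycles
#'   (normally equal to `pam`); `0` disables substitutions.
#' @return An object of class `evol_params`.
#' @export
evol_params <- function(pam, p_del = 0.55, zipf_exponent = 1.6,
                        max_indel_len = 50, ancestor_length = 200,
                        indel_rate = NULL, cycles = NULL) {
  stopifnot(length(pam) == 1L, pam >= 1, pam == round(pam),
            p_del > 0, p_del < 1, zipf_exponent > 1,
            max_indel_len >= 1, ancestor_length >= 1)
  if (!is.null(indel_rate))
    stopifnot(length(indel_rate) == 1L, indel_rate >= 0, indel_rate <= 1)
  if (!is.null(cycles))
    stopifnot(length(cycles) == 1L, cycles >= 0, cycles == round(cycles))
  structure(list(pam = as.integer(pam), p_del = p_del,
                 zipf_exponent = zipf_exponent,
                 max_indel_len = as.integer(max_indel_len),
                 ancestor_length = as.integer(ancestor_length),
                 indel_rate = indel_rate, cycles = cycles),
            class = "evol_params")
}

#' Console (non-homologous flank) geometry
#'
#' @param r Ratio of the total console length of a sequence to the ancestor
#'   length (0 disables consoles).
#' @param c Console asymmetry: the absolute difference of the two console
#'   lengths divided by their total, in `[0, 1]`; for sequence 1 the left
#'   console is the shorter one, for sequence 2 the right one.
#' @return An object of class `console_spec`.
#' @export
console_spec <- function(r = 0, c = 0) {
  stopifnot(length(r) == 1L, r >= 0, length(c) == 1L, c >= 0, c <= 1)
  structure(list(r = r, c = c), class = "console_spec")
}

#' Per-position indel probability as a function of PAM distance
#'
#' The empirical law `P_indel = 0.0224 - 0.0219 * exp(-0.01168 * PAM)`:
#' indels accumulate quickly at short distances and saturate near 2.24% per
#' position.
#'
#' @param pam Non-negative numeric PAM distance.
#' @return Probability of an indel event at a given position.
#' @export
indel_probability <- function(pam) {
  stopifnot(all(pam >= 0))
  0.0224 - 0.0219 * exp(-0.01168 * pam)
}

#' Draw indel lengths from the truncated Zipfian law
#'
#' `P(len = k)` is proportional to `k^-zipf_exponent` for
#' `k = 1..max_indel_len`.
#'
#' @param params An [evol_params()] object.
#' @param n Number of draws.
#' @return Integer vector of indel lengths.
#' @export
sample_indel_length <- function(params, n = 1) {
  k <- seq_len(params$max_indel_len)
  sample.int(params$max_indel_len, n, replace = TRUE,
             prob = k^(-params$zipf_exponent))
}

#' Generate a random Bernoulli ancestor sequence
#'
#' Residues are drawn i.i.d. from the background frequency vector.
#'
#' @param length Positive sequence length.
#' @param background Length-20 frequency vector summing to 1.
#' @return A residue sequence as a single character string.
#' @export
generate_ancestor <- function(length, background = mutation_model()$background) {
  if (length < 1) stop("'length' must be >= 1")
  if (abs(sum(background) - 1) > 1e-6)
    stop("'background' must sum to 1")
  aa_decode(sample.int(20L, length, replace = TRUE, prob = background))
}

## --- core evolution -------------------------------------------------------

## A core trace is a list(core = integer residue codes,
##                        origin = 1-based ancestor index or NA if inserted).

#' Incorporate insertions and deletions into an ancestor sequence
#'
#' Scans ancestor positions `1..L+1` left to right (position `L+1` admits
#' insertions at the terminus only).  At each position an indel occurs with
#' probability [indel_probability()]; it is a deletion with probability
#' `p_del` (removing a run of surviving ancestor sites starting there) and an
#' insertion otherwise (background-distributed residues placed before the
#' position).  Attempts that would distort the preset length law are
#' discarded whole: deletions overrunning the terminus or starting on an
#' already deleted site, and insertions beginning exactly at the elongation
#' of an earlier indel.
#'
#' The per-position RNG draw order (occurrence, then type, then length, then
#' — for accepted insertions — the inserted residues) is part of the
#' reproducibility contract.
#'
#' @param ancestor Residue sequence (character string or integer codes).
#' @param params An [evol_params()] object.
#' @param model A [mutation_model()] (supplies insertion composition).
#' @return A core trace: list with `core` (integer residue codes) and
#'   `origin` (parallel vector of 1-based ancestor indices, `NA` for
#'   inserted positions).
#' @export
apply_indels <- function(ancestor, params, model = mutation_model()) {
  anc <- if (is.character(ancestor)) aa_encode(ancestor) else as.integer(ancestor)
  L <- length(anc)
  if (L == 0L) stop("'ancestor' must be non-empty")
  p_indel <- if (is.null(params$indel_rate)) indel_probability(params$pam)
             else params$indel_rate
  deleted <- logical(L)
  block_ins <- logical(L + 1L)
  insertions <- vector("list", L + 1L)
  for (i in seq_len(L + 1L)) {
    if (runif(1) >= p_indel) next
    is_del <- runif(1) < params$p_del
    len <- sample_indel_length(params)
    if (is_del) {
      if (i > L || i + len - 1L > L) next      # overruns the terminus
      if (deleted[i]) next                     # begins on a deleted site
      deleted[i:(i + len - 1L)] <- TRUE
      block_ins[min(i + len, L + 1L)] <- TRUE  # elongation slot of this run
    } else {
      if (block_ins[i]) next                   # would elongate a prior indel
      insertions[[i]] <- sample.int(20L, len, replace = TRUE,
                                    prob = model$background)
      block_ins[i] <- TRUE
    }
  }
  core <- integer(0)
  origin <- integer(0)
  for (i in seq_len(L)) {
    if (!is.null(insertions[[i]])) {
      core <- c(core, insertions[[i]])
      origin <- c(origin, rep(NA_integer_, length(insertions[[i]])))
    }
    if (!deleted[i]) {
      core <- c(core, anc[i])
      origin <- c(origin, i)
    }
  }
  if (!is.null(insertions[[L + 1L]])) {
    core <- c(core, insertions[[L + 1L]])
    origin <- c(origin, rep(NA_integer_, length(insertions[[L + 1L]])))
  }
  list(core = core, origin = origin)
}

#' Apply cycles of PAM1 point mutations to a core trace
#'
#' Each surviving ancestor-derived position is resampled `cycles` times from
#' the PAM1 row of its current residue; inserted positions are never
#' point-mutated and origin records are unchanged.
#'
#' @param trace A core trace from [apply_indels()].
#' @param model A [mutation_model()].
#' @param cycles Number of PAM1 cycles (normally the PAM distance).
#' @return The mutated core trace.
#' @export
apply_point_mutations <- function(trace, model = mutation_model(), cycles) {
  stopifnot(cycles >= 0, cycles == round(cycles))
  idx <- which(!is.na(trace$origin))
  if (length(idx) == 0L || cycles == 0L) return(trace)
  cum <- t(apply(model$pam1, 1L, cumsum))
  mutated <- .mutate_cycles(trace$core[idx] - 1L, cum, as.integer(cycles)) + 1L
  trace$core[idx] <- mutated
  trace
}

evolve_core <- function(anc_codes, params, model) {
  tr <- apply_indels(anc_codes, params, model)
  cycles <- if (is.null(params$cycles)) params$pam else params$cycles
  apply_point_mutations(tr, model, cycles)
}

#' Console lengths implied by the ancestor length and a console spec
#'
#' The total console length is `T = round(L * r)`; the shorter console gets
#' `round(T * (1 - c) / 2)` residues and the longer one the remainder, so the
#' split is exact.  Sequence 1 carries the shorter console on the left,
#' sequence 2 on the right (the cores are shifted in opposite directions).
#'
#' @param ancestor_length Ancestor length `L`.
#' @param spec A [console_spec()].
#' @return Named integer vector `c(l1, r1, l2, r2)`.
#' @export
console_lengths <- function(ancestor_length, spec) {
  total <- round(ancestor_length * spec$r)
  shorter <- round(total * (1 - spec$c) / 2)
  longer <- total - shorter
  c(l1 = shorter, r1 = longer, l2 = longer, r2 = shorter)
}

#' Build one test pair with its gold-standard alignment
#'
#' Evolves two cores independently from the common ancestor (diverging
#' scheme) or keeps the first sequence equal to the ancestor (sequential
#' scheme), attaches independent random consoles, and composes the
#' gold-standard reference: the ordered list of full-sequence position pairs
#' descending from the same ancestor position.  Console positions are
#' unaligned by construction.
#'
#' @param ancestor Residue sequence (string or integer codes).
#' @param params An [evol_params()].
#' @param spec A [console_spec()].
#' @param model A [mutation_model()].
#' @param scheme `"diverging"` (two descendants of a common ancestor, the
#'   default) or `"sequential"` (ancestor vs descendant).
#' @return An object of class `test_pair`: list with character sequences
#'   `s1`, `s2`; 1-based inclusive core ranges `core1`, `core2`; the
#'   `reference` match-column matrix (columns `i`, `j`, 1-based full-sequence
#'   coordinates); and the generating `ancestor`, core codes `k1`, `k2` and
#'   origin maps `origin1`, `origin2`.
#' @export
build_test_pair <- function(ancestor, params, spec = console_spec(),
                            model = mutation_model(),
                            scheme = c("diverging", "sequential")) {
  scheme <- match.arg(scheme)
  anc <- if (is.character(ancestor)) aa_encode(ancestor) else as.integer(ancestor)
  L <- length(anc)
  t1 <- if (scheme == "diverging") evolve_core(anc, params, model)
        else list(core = anc, origin = seq_len(L))
  t2 <- evolve_core(anc, params, model)
  cl <- console_lengths(L, spec)
  consoles <- lapply(cl, function(n)
    if (n > 0) sample.int(20L, n, replace = TRUE, prob = model$background)
    else integer(0))
  s1 <- c(consoles$l1, t1$core, consoles$r1)
  s2 <- c(consoles$l2, t2$core, consoles$r2)
  shared <- sort(intersect(t1$origin[!is.na(t1$origin)],
                           t2$origin[!is.na(t2$origin)]))
  ref <- cbind(i = cl[["l1"]] + match(shared, t1$origin),
               j = cl[["l2"]] + match(shared, t2$origin))
  structure(list(
    s1 = aa_decode(s1), s2 = aa_decode(s2),
    core1 = c(start = cl[["l1"]] + 1L, end = cl[["l1"]] + length(t1$core)),
    core2 = c(start = cl[["l2"]] + 1L, end = cl[["l2"]] + length(t2$core)),
    reference = ref,
    ancestor = aa_decode(anc),
    k1 = t1$core, k2 = t2$core,
    origin1 = t1$origin, origin2 = t2$origin,
    scheme = scheme), class = "test_pair")
}

#' @export
print.test_pair <- function(x, ...) {
  cat(sprintf("test pair (%s scheme): |s1| = %d, |s2| = %d, %d reference columns\n",
              x$scheme, nchar(x$s1), nchar(x$s2), nrow(x$reference)))
  invisible(x)
}

#' Generate a reproducible set of test pairs
#'
#' All randomness flows from a single `set.seed(seed)` call; within each pair
#' the draw order is ancestor, core 1, core 2, then consoles L1, R1, L2, R2.
#'
#' @inheritParams build_test_pair
#' @param n_pairs Number of pairs (>= 1).
#' @param seed Integer RNG seed.
#' @return An object of class `test_set`.
#' @export
generate_test_set <- function(params, spec = console_spec(),
                              model = mutation_model(), n_pairs = 1000,
                              seed = 1, scheme = c("diverging", "sequential")) {
  scheme <- match.arg(scheme)
  if (n_pairs < 1) stop("'n_pairs' must be >= 1")
  set.seed(seed)
  pairs <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    anc <- generate_ancestor(params$ancestor_length, model$background)
    pairs[[k]] <- build_test_pair(anc, params, spec, model, scheme)
  }
  structure(list(pairs = pairs, params = params, spec = spec,
                 n_pairs = as.integer(n_pairs), seed = seed, scheme = scheme),
            class = "test_set")
}

#' @export
print.test_set <- function(x, ...) {
  cat(sprintf("test set: %d pairs, PAM %d, r = %g, c = %g (%s scheme, seed %s)\n",
              x$n_pairs, x$params$pam, x$spec$r, x$spec$c, x$scheme,
              format(x$seed)))
  invisible(x)
}

#' Identity and indel statistics of the gold-standard alignments
#'
#' `%id` is the mean (over pairs) fraction of residue-identical columns among
#' reference match columns; `%indel` is the mean fraction of gap columns
#' among all reference-alignment columns, where every core position absent
#' from the match list contributes one gap column and consoles contribute
#' nothing.  The `"ancestor_descendant"` scheme compares the ancestor with
#' the second (always evolved) core; `"descendant_descendant"` uses the
#' pair's own reference and requires a diverging-scheme set.
#'
#' @param ts A [generate_test_set()] result.
#' @param scheme Statistic flavour, see above.
#' @return Named numeric vector `c(id, indel)`, both in percent.
#' @export
reference_stats <- function(ts, scheme = c("ancestor_descendant",
                                           "descendant_descendant")) {
  scheme <- match.arg(scheme)
  if (!inherits(ts, "test_set") || ts$n_pairs == 0L)
    stop("'ts' must be a non-empty test_set")
  if (scheme == "descendant_descendant" && ts$scheme != "diverging")
    stop("descendant_descendant statistics need a diverging-scheme set")
  per_pair <- vapply(ts$pairs, function(p) {
    anc <- aa_encode(p$ancestor)
    if (scheme == "ancestor_descendant") {
      surv <- !is.na(p$origin2)
      n_match <- sum(surv)
      id <- if (n_match > 0) mean(p$k2[surv] == anc[p$origin2[surv]]) else NA_real_
      gap_cols <- (length(anc) - n_match) + sum(!surv)
    } else {
      n_match <- nrow(p$reference)
      i1 <- p$reference[, "i"] - p$core1[["start"]] + 1L
      i2 <- p$reference[, "j"] - p$core2[["start"]] + 1L
      id <- if (n_match > 0) mean(p$k1[i1] == p$k2[i2]) else NA_real_
      gap_cols <- (length(p$k1) - n_match) + (length(p$k2) - n_match)
    }
    c(id, gap_cols / (n_match + gap_cols))
  }, numeric(2))
  c(id = 100 * mean(per_pair[1, ], na.rm = TRUE),
    indel = 100 * mean(per_pair[2, ]))
}
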