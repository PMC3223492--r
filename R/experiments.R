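#' Align and evaluate every pair of a test set
#'
#' Runs the chosen aligner on each pair of the set and aggregates per-pair
#' accuracy and confidence.
#'
#' @param ts A `test_set`.
#' @param mode `"global"` or `"local"`.
#' @param matrix,gap Aligner parameterization; defaults follow the mode
#'   (PAM250 with 14/2 for global, Gonnet250 with 10/0.5 for local).
#' @return Named numeric vector `c(accuracy, confidence)` in percent.
#' @export
evaluate_set <- function(ts, mode = c("global", "local"),
                         matrix = NULL, gap = NULL) {
  mode <- match.arg(mode)
  if (is.null(matrix))
    matrix <- scoring_matrix(if (mode == "global") "PAM250" else "Gonnet250")
  if (is.null(gap))
    gap <- if (mode == "global") gap_penalty(14, 2) else gap_penalty(10, 0.5)
  aligner <- if (mode == "global") align_global else align_local
  res <- lapply(ts$pairs, function(p)
    evaluate_pair(aligner(p$s1, p$s2, matrix, gap), p))
  aggregate_quality(res)
}

#' Configuration of the full quality sweep
#'
#' The default grid is the full study design: 4 PAM distances, console
#' lengths r of 0-200% with 11 asymmetry values each for r > 0 and a single
#' console-free cell per distance — 224 distinct test-set configurations.
#'
#' @param pam_values Per-branch PAM distances.
#' @param r_values Console length ratios (0 means no consoles).
#' @param c_values Console asymmetries used for every `r > 0`.
#' @param n_pairs Pairs per test set (1000 at full scale; scaled-down runs
#'   use 100-200).
#' @param seed Master seed; each grid cell runs on `seed + cell index`.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(pam_values = c(30, 60, 120, 240),
                         r_values = c(0, 0.1, 0.2, 0.5, 1, 2),
                         c_values = seq(0, 1, by = 0.1),
                         n_pairs = 1000, seed = 1) {
  structure(list(pam_values = pam_values, r_values = r_values,
                 c_values = c_values, n_pairs = n_pairs, seed = seed),
            class = "sweep_config")
}

#' Enumerate the distinct test-set configurations of a sweep
#'
#' @param cfg A [sweep_config()].
#' @return Data frame with columns `pam`, `r`, `c` (one row per test set;
#'   `r = 0` collapses all asymmetries into a single cell).
#' @export
enumerate_cells <- function(cfg) {
  cells <- expand.grid(c = cfg$c_values, r = cfg$r_values[cfg$r_values > 0],
                       pam = cfg$pam_values)[, c("pam", "r", "c")]
  if (any(cfg$r_values == 0))
    cells <- rbind(expand.grid(pam = cfg$pam_values, r = 0, c = 0), cells)
  cells <- cells[order(cells$pam, cells$r, cells$c), ]
  rownames(cells) <- NULL
  cells
}

#' Run the quality sweep over PAM distance, console length and asymmetry
#'
#' For every grid cell: generate an independent test set (seeded by the
#' master seed plus the cell index), align every pair globally and locally,
#' evaluate against the gold standard, and aggregate.  Deterministic given
#' the configuration.
#'
#' @param cfg A [sweep_config()].
#' @param model A [mutation_model()].
#' @param modes Which aligners to run.
#' @param out Optional path of a TSV file to which completed rows are
#'   appended as the sweep progresses (long sweeps are resumable by cell).
#' @param verbose Print progress.
#' @return Data frame with one row per (pam, r, c, mode): columns `pam`,
#'   `r`, `c`, `mode`, `accuracy`, `confidence`, `n_pairs`.
#' @export
run_quality_sweep <- function(cfg, model = mutation_model(),
                              modes = c("global", "local"), out = NULL,
                              verbose = FALSE) {
  cells <- enumerate_cells(cfg)
  rows <- vector("list", nrow(cells) * length(modes))
  n <- 0L
  for (k in seq_len(nrow(cells))) {
    pam <- cells$pam[k]
    ts <- generate_test_set(evol_params(pam), console_spec(cells$r[k], cells$c[k]),
                            model, cfg$n_pairs, seed = cfg$seed + k)
    for (mode in modes) {
      q <- evaluate_set(ts, mode)
      n <- n + 1L
      rows[[n]] <- data.frame(pam = pam, r = cells$r[k], c = cells$c[k],
                              mode = mode, accuracy = q[["accuracy"]],
                              confidence = q[["confidence"]],
                              n_pairs = cfg$n_pairs)
      if (!is.null(out))
        write.table(rows[[n]], out, sep = "\t", row.names = FALSE,
                    col.names = !file.exists(out), append = file.exists(out),
                    quote = FALSE)
    }
    if (verbose)
      message(sprintf("cell %d/%d: PAM %d r %.1f c %.1f", k, nrow(cells),
                      pam, cells$r[k], cells$c[k]))
  }
  do.call(rbind, rows[seq_len(n)])
}

#' Sensitivity of global alignment quality to the scoring matrix and penalties
#'
#' Generates sequential-scheme (ancestor vs descendant) test sets at the
#' given distances and aligns each globally under every combination of
#' matrix, gap-open and gap-extension penalty.
#'
#' @param pam_values Ancestor-descendant PAM distances of the test sets.
#' @param matrices Named list of substitution matrices (e.g. PAM log-odds at
#'   several distances via [make_log_odds()]).
#' @param gop_values,gep_values Penalty grids.
#' @param n_pairs Pairs per set.
#' @param seed Master seed (one set per distance, seeded `seed + index`).
#' @param model A [mutation_model()].
#' @return Data frame with columns `pam`, `matrix`, `gop`, `gep`,
#'   `accuracy`, `confidence`.
#' @export
run_matrix_sweep <- function(pam_values, matrices, gop_values = 14,
                             gep_values = 2, n_pairs = 200, seed = 1,
                             model = mutation_model()) {
  stopifnot(length(pam_values) >= 1, length(matrices) >= 1,
            length(gop_values) >= 1, length(gep_values) >= 1)
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, function(m)
      attr(m, "name") %||% "matrix", character(1))
  rows <- list()
  for (k in seq_along(pam_values)) {
    ts <- generate_test_set(evol_params(pam_values[k]), console_spec(0, 0),
                            model, n_pairs, seed = seed + k,
                            scheme = "sequential")
    for (mname in names(matrices)) for (gop in gop_values)
      for (gep in gep_values) {
        q <- evaluate_set(ts, "global", matrices[[mname]],
                          gap_penalty(gop, gep))
        rows[[length(rows) + 1L]] <-
          data.frame(pam = pam_values[k], matrix = mname, gop = gop,
                     gep = gep, accuracy = q[["accuracy"]],
                     confidence = q[["confidence"]])
      }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random-alignment density experiment
#'
#' Seeded driver over [estimate_density_curve()].
#'
#' @param lengths Sequence lengths to probe.
#' @param n_reps Pairs per length.
#' @param seed RNG seed.
#' @param matrix,gap Aligner parameterization.
#' @return Data frame with columns `length` and `density`.
#' @export
run_density_experiment <- function(lengths = c(10, 25, 50, 100, 200, 400, 600),
                                   n_reps = 1000, seed = 1,
                                   matrix = scoring_matrix("PAM250"),
                                   gap = gap_penalty(14, 2)) {
  set.seed(seed)
  estimate_density_curve(lengths, matrix, gap, n_reps)
}

#' Slope-zone experiment: empirical collapse versus analytic prediction
#'
#' Sweeps the console asymmetry grid at fixed PAM and console length,
#' measuring global-alignment accuracy per cell, then fits the density model
#' on the first cell's set and predicts the critical asymmetry via
#' [critical_asymmetry()].  The empirical slope zone is localized with
#' [locate_slope_zone()].
#'
#' @param pam Per-branch PAM distance.
#' @param r Console length ratio (> 0).
#' @param c_values Asymmetry grid.
#' @param n_pairs Pairs per cell.
#' @param seed Master seed.
#' @param model A [mutation_model()].
#' @param matrix,gap Global-aligner parameterization.
#' @param n_reps Monte-Carlo replicates for the random densities.
#' @return An object of class `slope_experiment`: list with `curve` (data
#'   frame of `c`, `accuracy`, `confidence`), `params`
#'   ([density_params()]), `c_star` and `zone`.
#' @export
run_slope_experiment <- function(pam, r, c_values = seq(0, 1, by = 0.1),
                                 n_pairs = 200, seed = 1,
                                 model = mutation_model(),
                                 matrix = scoring_matrix("PAM250"),
                                 gap = gap_penalty(14, 2), n_reps = 500) {
  stopifnot(r > 0)
  acc <- conf <- numeric(length(c_values))
  first_set <- NULL
  for (k in seq_along(c_values)) {
    ts <- generate_test_set(evol_params(pam), console_spec(r, c_values[k]),
                            model, n_pairs, seed = seed + k)
    if (k == 1L) first_set <- ts
    q <- evaluate_set(ts, "global", matrix, gap)
    acc[k] <- q[["accuracy"]]
    conf[k] <- q[["confidence"]]
  }
  set.seed(seed)
  params <- fit_density_params(first_set, matrix, gap, n_reps)
  structure(list(curve = data.frame(c = c_values, accuracy = acc,
                                    confidence = conf),
                 params = params, c_star = critical_asymmetry(params),
                 zone = locate_slope_zone(c_values, acc)),
            class = "slope_experiment")
}

#' @export
print.slope_experiment <- function(x, ...) {
  cat("slope-zone experiment\n")
  print(x$curve, row.names = FALSE)
  cat(sprintf("predicted critical asymmetry c* = %s\n",
              if (is.na(x$c_star)) "none" else sprintf("%.3f", x$c_star)))
  cat(sprintf("empirical slope zone: midpoint %.2f (%.2f - %.2f)\n",
              x$zone$midpoint, x$zone$lower, x$zone$upper))
  invisible(x)
}

#' @export
#' @importFrom graphics abline legend lines rect
plot.slope_experiment <- function(x, ...) {
  plot(x$curve$c, x$curve$accuracy, type = "b", pch = 19,
       xlab = "console asymmetry c", ylab = "accuracy (%)",
       ylim = c(0, 100), ...)
  lines(x$curve$c, x$curve$confidence, type = "b", pch = 1, lty = 2)
  rect(x$zone$lower, 0, x$zone$upper, 100,
       col = grDevices::adjustcolor("grey", 0.3), border = NA)
  if (!is.na(x$c_star)) abline(v = x$c_star, col = "red")
  legend("bottomleft", c("accuracy", "confidence", "predicted c*"),
         lty = c(1, 2, 1), pch = c(19, 1, NA),
         col = c("black", "black", "red"), bty = "n")
  invisible(x)
}
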