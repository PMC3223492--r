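#' @useDynLib alnbench, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif
#' @importFrom utils read.table write.table
NULL

.pkg_cache <- new.env(parent = emptyenv())

#' The amino-acid alphabet used throughout the package
#'
#' All sequences, frequency vectors and 20 x 20 matrices in this package are
#' indexed in the conventional one-letter alphabetical order
#' `ARNDCQEGHILKMFPSTWYV`; matrices read from files are re-indexed to this
#' order on load.
#'
#' @return Character vector of the 20 one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

## integer coding (1..20) <-> character sequences
aa_encode <- function(s) {
  if (length(s) == 1L && nchar(s) != 1L) s <- strsplit(s, "")[[1]]
  idx <- match(toupper(s), aa_alphabet())
  if (anyNA(idx)) {
    bad <- unique(s[is.na(idx)])
    stop("unknown residue symbol(s): ", paste(bad, collapse = ", "))
  }
  idx
}

aa_decode <- function(idx) paste(aa_alphabet()[idx], collapse = "")

#' Read or write a square scoring/probability matrix in NCBI-style text format
#'
#' The format is a header row of residue letters followed by one labelled row
#' per residue.  On reading, rows and columns are re-indexed to
#' [aa_alphabet()] order.
#'
#' @param path File path.
#' @param m A 20 x 20 numeric matrix with residue dimnames (for writing).
#' @param digits Number of significant digits written.
#' @return `read_score_matrix` returns a 20 x 20 numeric matrix with residue
#'   dimnames; `write_score_matrix` returns `path` invisibly.
#' @export
read_score_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(tab)
  rownames(m) <- rownames(tab)
  alpha <- aa_alphabet()
  if (!all(alpha %in% rownames(m)) || !all(alpha %in% colnames(m)))
    stop("matrix file does not cover the 20-letter amino-acid alphabet: ", path)
  m[alpha, alpha]
}

#' @rdname read_score_matrix
#' @export
write_score_matrix <- function(m, path, digits = 10) {
  stopifnot(is.matrix(m), nrow(m) == 20, ncol(m) == 20)
  alpha <- aa_alphabet()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("  ", alpha), collapse = " "), con)
  for (i in seq_len(20))
    writeLines(paste(c(alpha[i], format(m[i, ], digits = digits, trim = TRUE,
                                        scientific = FALSE)), collapse = " "), con)
  invisible(path)
}

.extdata <- function(file) {
  system.file("extdata", file, package = "alnbench", mustWork = TRUE)
}

#' Built-in substitution scoring matrices
#'
#' Returns one of the package's embedded 20 x 20 substitution weight matrices,
#' all on the 10*log10 (half-bit-like) log-odds scale:
#' * `"PAM250"` — real-valued 250-PAM Dayhoff log-odds (the package default for
#'   global alignment; keeping the unrounded values reproduces published
#'   mean-random-score figures that integer rounding distorts),
#' * `"PAM250int"` — the classical integer-rounded PAM250,
#' * `"Gonnet250"` — the Gonnet et al. (1992) 250-PAM matrix at its native
#'   fractional scale (the default for local alignment).
#'
#' @param name Matrix name (case sensitive), or a path handled by
#'   [read_score_matrix()].
#' @return Numeric 20 x 20 matrix with residue dimnames and a `"name"`
#'   attribute.
#' @export
scoring_matrix <- function(name = c("PAM250", "Gonnet250", "PAM250int")) {
  name <- match.arg(name)
  key <- paste0("mat_", name)
  if (is.null(.pkg_cache[[key]])) {
    file <- switch(name,
      PAM250 = "PAM250.txt", PAM250int = "PAM250int.txt",
      Gonnet250 = "gonnet250.txt")
    m <- read_score_matrix(.extdata(file))
    attr(m, "name") <- name
    .pkg_cache[[key]] <- m
  }
  .pkg_cache[[key]]
}

#' The Dayhoff PAM1 mutation model
#'
#' The generative engine of the sequence evolver: the 20 x 20 PAM1 transition
#' probability matrix (row = current residue, column = next residue, one PAM
#' unit, i.e. ~1% accepted point mutations) together with the Dayhoff
#' background amino-acid frequencies.  The matrix is derived from the Dayhoff
#' exchangeability model, scaled so that the background-weighted probability
#' of change per site is exactly 1%.
#'
#' @return An object of class `mutation_model`: a list with components
#'   `alphabet`, `pam1` (20 x 20 row-stochastic matrix) and `background`
#'   (length-20 frequency vector summing to 1).
#' @export
mutation_model <- function() {
  if (is.null(.pkg_cache$model)) {
    pam1 <- read_score_matrix(.extdata("dayhoff_pam1.txt"))
    pam1 <- pam1 / rowSums(pam1)
    bftab <- read.table(.extdata("dayhoff_freqs.txt"),
                        col.names = c("aa", "freq"))
    bf <- bftab$freq[match(aa_alphabet(), bftab$aa)]
    bf <- bf / sum(bf)
    m <- structure(list(alphabet = aa_alphabet(), pam1 = pam1,
                        background = bf), class = "mutation_model")
    validate_mutation_model(m)
    .pkg_cache$model <- m
  }
  .pkg_cache$model
}

validate_mutation_model <- function(m) {
  stopifnot(inherits(m, "mutation_model"))
  if (max(abs(rowSums(m$pam1) - 1)) > 1e-9)
    stop("PAM1 rows must sum to 1")
  if (abs(sum(m$background) - 1) > 1e-9 || any(m$background <= 0))
    stop("background frequencies must be positive and sum to 1")
  invisible(m)
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("Dayhoff PAM1 mutation model\n")
  cat(sprintf("  expected conservation per PAM unit: %.4f\n",
              sum(x$background * diag(x$pam1))))
  invisible(x)
}

#' Integer power of the PAM1 transition matrix
#'
#' @param model A [mutation_model()].
#' @param n Non-negative integer number of PAM1 steps.
#' @return The 20 x 20 row-stochastic `n`-step transition matrix.
#' @export
pam_power <- function(model, n) {
  stopifnot(inherits(model, "mutation_model"))
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop("'n' must be a single non-negative integer")
  p <- diag(20)
  b <- model$pam1
  n <- as.integer(n)
  while (n > 0L) { # exponentiation by squaring
    if (n %% 2L == 1L) p <- p %*% b
    b <- b %*% b
    n <- n %/% 2L
  }
  dimnames(p) <- dimnames(model$pam1)
  p
}

#' Expected fraction of identical residues after PAM evolution
#'
#' For the sequential ("ancestor_descendant") scheme this is the probability
#' that a site still carries its ancestral residue after `n` PAM1 steps,
#' `sum_i f_i (P^n)_ii`.  For the diverging ("descendant_descendant") scheme
#' both branches take `n` independent steps from the common ancestor and the
#' expectation is `sum_i f_i sum_a (P^n)_ia^2`.
#'
#' @inheritParams pam_power
#' @param scheme `"ancestor_descendant"` or `"descendant_descendant"`.
#' @return Expected identity as a fraction in `[0, 1]`.
#' @export
expected_identity <- function(model, n,
                              scheme = c("ancestor_descendant",
                                         "descendant_descendant")) {
  scheme <- match.arg(scheme)
  p <- pam_power(model, n)
  f <- model$background
  switch(scheme,
    ancestor_descendant = sum(f * diag(p)),
    descendant_descendant = sum(f * rowSums(p^2)))
}

#' Mean substitution score of two independent random residues
#'
#' Computes `sum_i sum_j p_i p_j S_ij`, the expected per-column score when two
#' unrelated background-distributed residues are compared.  For homology-tuned
#' matrices this is negative: random matches are penalized on average.
#'
#' @param matrix 20 x 20 substitution weight matrix.
#' @param background Length-20 frequency vector summing to 1 (default: the
#'   Dayhoff frequencies).
#' @return The expected score per column (a scalar).
#' @export
mean_random_score <- function(matrix, background = mutation_model()$background) {
  if (!is.matrix(matrix) || nrow(matrix) != length(background) ||
      ncol(matrix) != length(background))
    stop("'matrix' must be square with dimension matching 'background'")
  if (abs(sum(background) - 1) > 1e-6)
    stop("'background' must sum to 1")
  drop(background %*% matrix %*% background)
}

#' Derive a PAM-n log-odds scoring matrix from the mutation model
#'
#' Computes `S_ij = scale * log10((P^n)_ij / f_j)` and symmetrizes by
#' averaging with the transpose.  With `scale = 10` and `n = 250` this
#' reproduces the classical PAM250 matrix up to integer rounding.
#'
#' @inheritParams pam_power
#' @param n Positive integer PAM distance.
#' @param scale Multiplier applied to the base-10 log-odds (default 10, the
#'   conventional PAM scale); values are not rounded.
#' @return Numeric 20 x 20 scoring matrix with a `"name"` attribute `PAMn`.
#' @export
make_log_odds <- function(model, n, scale = 10) {
  stopifnot(inherits(model, "mutation_model"))
  if (n < 1) stop("'n' must be a positive integer")
  if (any(model$background <= 0)) stop("background entries must be positive")
  p <- pam_power(model, n)
  lo <- scale * log10(sweep(p, 2, model$background, "/"))
  lo <- (lo + t(lo)) / 2
  attr(lo, "name") <- paste0("PAM", n)
  lo
}
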