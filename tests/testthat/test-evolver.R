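test_that("the indel-rate law matches its printed constants", {
  expect_equal(indel_probability(0), 0.0005)
  expect_equal(indel_probability(1e6), 0.0224)
  expect_equal(indel_probability(120), 0.01701, tolerance = 1e-5 / 0.017)
  expect_error(indel_probability(-3))
})

test_that("indel lengths follow the truncated Zipf law", {
  p <- evol_params(30, zipf_exponent = 1.7, max_indel_len = 50)
  set.seed(1)
  draws <- sample_indel_length(p, 1e5)
  expect_true(all(draws >= 1 & draws <= 50))
  # analytic mass ratio P(1)/P(2) = 2^1.7, within 3 sigma of the MC estimate
  n1 <- sum(draws == 1)
  n2 <- sum(draws == 2)
  ratio <- n1 / n2
  se <- ratio * sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(ratio - 2^1.7), 3 * se)
  p1 <- evol_params(30, max_indel_len = 1)
  expect_true(all(sample_indel_length(p1, 100) == 1))
})

test_that("ancestors are Bernoulli sequences with background composition", {
  expect_error(generate_ancestor(0), ">= 1")
  expect_error(generate_ancestor(10, rep(1, 20)), "sum to 1")
  set.seed(7)
  a1 <- generate_ancestor(200)
  set.seed(7)
  expect_identical(generate_ancestor(200), a1)
  m <- mutation_model()
  set.seed(11)
  big <- paste(replicate(500, generate_ancestor(200)), collapse = "")
  pooled <- table(factor(strsplit(big, "")[[1]], levels = aa_alphabet()))
  expect_gt(stats::chisq.test(pooled, p = m$background)$p.value, 1e-4)
})

test_that("indel placement respects the collision rules and the target rate", {
  m <- mutation_model()
  p0 <- evol_params(30, indel_rate = 0)
  set.seed(3)
  anc <- generate_ancestor(50)
  tr <- apply_indels(anc, p0, m)
  expect_identical(aa_decode(tr$core), anc)
  expect_identical(tr$origin, 1:50)
  # accepted indel events per position approximate the Eq-style law at PAM 30
  p30 <- evol_params(30)
  set.seed(5)
  n_anc <- 2000
  L <- 200
  events <- 0
  for (k in seq_len(n_anc)) {
    tr <- apply_indels(sample.int(20, L, TRUE, prob = m$background), p30, m)
    surv <- tr$origin[!is.na(tr$origin)]
    n_del_runs <- sum(diff(c(0L, surv)) > 1L) + (length(surv) > 0 && max(surv) < L)
    n_ins_runs <- sum(diff(c(FALSE, is.na(tr$origin))) == 1L)
    events <- events + n_del_runs + n_ins_runs
  }
  n_pos <- n_anc * (L + 1)
  p_hat <- events / n_pos
  p_exp <- indel_probability(30)
  se <- sqrt(p_exp * (1 - p_exp) / n_pos)
  # small downward bias from discarded attempts is expected; 3 sigma band
  expect_lt(abs(p_hat - p_exp), 3 * se + 0.03 * p_exp)
  # origins always strictly increasing, each ancestor site used at most once
  expect_true(all(diff(surv) >= 1))
  expect_false(any(duplicated(surv)))
})

test_that("point mutation cycles reproduce the matrix-power identity decay", {
  m <- mutation_model()
  ident <- m
  ident$pam1 <- diag(20)
  tr <- list(core = aa_encode("ACDEFGHIKLMNPQRSTVWY"), origin = 1:20)
  expect_identical(apply_point_mutations(tr, ident, 50)$core, tr$core)
  # inserted positions are never mutated
  tr_ins <- list(core = aa_encode("AAAAA"), origin = c(1L, NA, 2L, NA, 3L))
  set.seed(2)
  out <- apply_point_mutations(tr_ins, m, 200)
  expect_identical(out$core[c(2, 4)], tr_ins$core[c(2, 4)])
  expect_identical(out$origin, tr_ins$origin)
  # identity after 30 cycles matches the matrix-power expectation within 3 sigma
  set.seed(13)
  n_sites <- 1e5
  start <- sample.int(20, n_sites, TRUE, prob = m$background)
  tr_big <- list(core = start, origin = seq_len(n_sites))
  ended <- apply_point_mutations(tr_big, m, 30)$core
  frac <- mean(ended == start)
  p_exp <- expected_identity(m, 30, "ancestor_descendant")
  expect_lt(abs(frac - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n_sites))
  # one cycle follows the PAM1 row of the starting residue
  for (res in c("A", "W")) {
    set.seed(17)
    n <- 2e4
    tr1 <- list(core = rep(aa_encode(res), n), origin = seq_len(n))
    out1 <- apply_point_mutations(tr1, m, 1)$core
    emp <- tabulate(out1, 20) / n
    row <- m$pam1[aa_encode(res), ]
    expect_lt(sum(abs(emp - row)) / 2, 0.02)  # total variation
    d <- aa_encode(res)
    expect_lt(abs(emp[d] - row[d]), 4 * sqrt(row[d] * (1 - row[d]) / n))
  }
})

test_that("console lengths follow the rounding contract", {
  expect_identical(console_lengths(200, console_spec(0.1, 0.1)),
                   c(l1 = 9, r1 = 11, l2 = 11, r2 = 9))
  cl <- console_lengths(200, console_spec(0.5, 0))
  expect_lte(abs(cl[["l1"]] - cl[["r1"]]), 1)
  expect_identical(console_lengths(200, console_spec(1, 1)),
                   c(l1 = 0, r1 = 200, l2 = 200, r2 = 0))
  cl <- console_lengths(200, console_spec(0.37, 0.43))
  expect_equal(cl[["l1"]] + cl[["r1"]], round(200 * 0.37))
  expect_identical(cl[["l1"]], cl[["r2"]])
  expect_identical(cl[["r1"]], cl[["l2"]])
})

test_that("with all rates zeroed the pair builder is the identity pipeline", {
  m <- mutation_model()
  set.seed(5)
  pair <- build_test_pair(generate_ancestor(30), frozen_params(), console_spec(0, 0), m)
  expect_identical(pair$s1, pair$ancestor)
  expect_identical(pair$s2, pair$ancestor)
  expect_equal(pair$reference, cbind(i = 1:30, j = 1:30))
})

test_that("the reference composition agrees with an independent recomposition", {
  m <- mutation_model()
  set.seed(21)
  for (rep in 1:5) {
    pair <- build_test_pair(generate_ancestor(60), evol_params(120),
                            console_spec(0.3, 0.4), m)
    # independent oracle: scan every (core1, core2) position pair directly
    ref2 <- NULL
    for (a in seq_along(pair$origin1)) for (b in seq_along(pair$origin2)) {
      if (!is.na(pair$origin1[a]) && !is.na(pair$origin2[b]) &&
          pair$origin1[a] == pair$origin2[b])
        ref2 <- rbind(ref2, c(pair$core1[["start"]] - 1L + a,
                              pair$core2[["start"]] - 1L + b))
    }
    if (is.null(ref2)) ref2 <- matrix(integer(0), 0, 2)
    expect_equal(unname(pair$reference), unname(ref2))
    # invariants: strictly increasing in both coordinates, bounded by cores
    expect_true(all(diff(pair$reference[, "i"]) > 0))
    expect_true(all(diff(pair$reference[, "j"]) > 0))
    expect_lte(nrow(pair$reference),
               min(length(pair$k1), length(pair$k2)))
    # length bookkeeping: sequence = left console + core + right console
    cl <- console_lengths(60, console_spec(0.3, 0.4))
    expect_equal(nchar(pair$s1), cl[["l1"]] + length(pair$k1) + cl[["r1"]])
    expect_equal(nchar(pair$s2), cl[["l2"]] + length(pair$k2) + cl[["r2"]])
  }
})

test_that("test sets are reproducible from their seed", {
  m <- mutation_model()
  ts1 <- generate_test_set(evol_params(60), console_spec(0.2, 0.5), m, 5, seed = 99)
  ts2 <- generate_test_set(evol_params(60), console_spec(0.2, 0.5), m, 5, seed = 99)
  expect_identical(ts1$pairs, ts2$pairs)
  expect_error(generate_test_set(evol_params(60), n_pairs = 0), ">= 1")
})

test_that("reference statistics recover the evolution model's expectations", {
  m <- mutation_model()
  ts0 <- generate_test_set(frozen_params(), console_spec(0, 0), m, 5, seed = 1)
  expect_equal(reference_stats(ts0, "ancestor_descendant"),
               c(id = 100, indel = 0))
  expect_equal(reference_stats(ts0, "descendant_descendant"),
               c(id = 100, indel = 0))
  # diverging at PAM approximately equals sequential at 2*PAM in identity...
  ts30 <- generate_test_set(evol_params(30), console_spec(0, 0), m, 300, seed = 2)
  ts60 <- generate_test_set(evol_params(60), console_spec(0, 0), m, 300, seed = 3)
  dd <- reference_stats(ts30, "descendant_descendant")
  ad <- reference_stats(ts60, "ancestor_descendant")
  expect_lt(abs(dd[["id"]] - ad[["id"]]), 2)
  # ...but carries strictly more indel columns
  expect_gt(dd[["indel"]], ad[["indel"]])
  # sequential-scheme sets refuse descendant-descendant statistics
  seqset <- generate_test_set(evol_params(30), console_spec(0, 0), m, 2,
                              seed = 4, scheme = "sequential")
  expect_error(reference_stats(seqset, "descendant_descendant"), "diverging")
})
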