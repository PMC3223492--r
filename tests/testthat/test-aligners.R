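toy_mat <- scoring_matrix("PAM250int")
toy_gap <- gap_penalty(4, 1)

test_that("global and local DP scores equal brute-force enumeration", {
  abc <- aa_encode("ARN")  # three-letter reduced residue set
  pool <- c(enum_seqs(abc, 1), enum_seqs(abc, 2), enum_seqs(abc, 3))
  set.seed(31)
  # exhaustive over short pairs, random sample of longer ones
  pairs <- c(
    lapply(1:150, function(k) list(sample(pool, 1)[[1]], sample(pool, 1)[[1]])),
    lapply(1:25, function(k) list(as.integer(sample(abc, sample(4:5, 1), TRUE)),
                                  as.integer(sample(abc, sample(4:5, 1), TRUE)))))
  for (pr in pairs) {
    s1 <- aa_decode(pr[[1]])
    s2 <- aa_decode(pr[[2]])
    g <- align_global(s1, s2, toy_mat, toy_gap)
    expect_equal(g$score,
                 bf_global_score(pr[[1]], pr[[2]], toy_mat, toy_gap$gop, toy_gap$gep))
    expect_equal(score_alignment(g, toy_mat, toy_gap), g$score, tolerance = 1e-9)
    l <- align_local(s1, s2, toy_mat, toy_gap)
    expect_equal(l$score,
                 bf_local_score(pr[[1]], pr[[2]], toy_mat, toy_gap$gop, toy_gap$gep))
    expect_gte(l$score, 0)
    if (nrow(l$columns) > 0)
      expect_equal(score_alignment(l, toy_mat, toy_gap), l$score, tolerance = 1e-9)
  }
})

test_that("identical sequences align on the diagonal at their self-score", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  a <- align_global(s, s)
  expect_equal(a$columns, cbind(i = 1:20, j = 1:20))
  cs <- aa_encode(s)
  expect_equal(a$score, sum(diag(scoring_matrix("PAM250"))[cs]))
})

test_that("forced single gaps and degenerate inputs behave as specified", {
  m <- scoring_matrix("PAM250")
  a <- align_global("AA", "A", m, gap_penalty(14, 2))
  expect_equal(a$score, m["A", "A"] - (14 + 2))
  expect_error(align_global("", "A"), "non-empty")
  expect_error(align_global("AB1", "AA"), "B|1")  # names the offending symbol
})

test_that("local alignment returns the empty alignment when nothing scores", {
  m <- scoring_matrix("PAM250")
  expect_lt(m["W", "G"], 0)
  a <- align_local("W", "G", m, gap_penalty(14, 2))
  expect_equal(a$score, 0)
  expect_equal(nrow(a$columns), 0L)
  expect_equal(score_alignment(a, m, gap_penalty(14, 2)), 0)
})

test_that("a conserved block embedded in hostile flanks is recovered exactly", {
  # every cross-flank and flank-block comparison scores negative under
  # Gonnet250, so the optimum is exactly the embedded diagonal
  block <- "WWCHKYWRHW"
  s1 <- paste0(strrep("G", 15), block, strrep("G", 15))
  s2 <- paste0(strrep("P", 12), block, strrep("P", 18))
  a <- align_local(s1, s2)
  expect_equal(a$columns, cbind(i = 16:25, j = 13:22))
})

test_that("alignment scores respect symmetry and penalty monotonicity", {
  set.seed(43)
  for (k in 1:10) {
    s1 <- generate_ancestor(25)
    s2 <- generate_ancestor(20)
    for (fn in list(align_global, align_local)) {
      expect_equal(fn(s1, s2)$score, fn(s2, s1)$score, tolerance = 1e-9)
    }
    sc <- vapply(c(5, 10, 20), function(gop)
      align_global(s1, s2, gap = gap_penalty(gop, 2))$score, numeric(1))
    expect_true(all(diff(sc) <= 1e-12))
  }
})

test_that("scores agree with an independent aligner implementation", {
  skip_if_not_installed("Biostrings")
  m <- scoring_matrix("PAM250int")
  set.seed(47)
  for (k in 1:10) {
    s1 <- generate_ancestor(40)
    s2 <- generate_ancestor(35)
    bs_g <- Biostrings::pairwiseAlignment(s1, s2, substitutionMatrix = unclass(m),
                                          gapOpening = 14, gapExtension = 2,
                                          type = "global", scoreOnly = TRUE)
    expect_equal(align_global(s1, s2, m, gap_penalty(14, 2))$score, bs_g)
    bs_l <- Biostrings::pairwiseAlignment(s1, s2, substitutionMatrix = unclass(m),
                                          gapOpening = 10, gapExtension = 1,
                                          type = "local", scoreOnly = TRUE)
    expect_equal(align_local(s1, s2, m, gap_penalty(10, 1))$score, max(bs_l, 0))
  }
})

test_that("score_alignment matches hand arithmetic and flags malformed input", {
  m <- scoring_matrix("PAM250")
  # three columns: match, then a length-2 gap in sequence 2
  a <- structure(list(columns = cbind(i = c(1L, 2L, 3L), j = c(1L, NA, NA)),
                      score = NA_real_, mode = "global",
                      s1 = "ARN", s2 = "A"), class = "pairwise_alignment")
  expect_equal(score_alignment(a, m, gap_penalty(14, 2)),
               m["A", "A"] - (14 + 2 * 2))
  bad <- a
  bad$columns <- cbind(i = c(1L, NA), j = c(1L, NA))
  expect_error(score_alignment(bad, m), "gap, gap")
})

test_that("global alignments cover both sequences exactly once", {
  set.seed(53)
  for (k in 1:5) {
    s1 <- generate_ancestor(30)
    s2 <- generate_ancestor(26)
    a <- align_global(s1, s2)
    ii <- a$columns[, 1L]
    jj <- a$columns[, 2L]
    expect_identical(ii[!is.na(ii)], 1:30)
    expect_identical(jj[!is.na(jj)], 1:26)
    expect_false(any(is.na(ii) & is.na(jj)))
  }
})
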