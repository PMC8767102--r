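# Profile-HMM construction and bit-score search.

test_that("match emissions follow the weighted-count pseudocount rule", {
  # two identical rows, uniform weights/background: a column of two As gives
  # (2 + 1 * 0.05) / (2 + 1) for A and 0.05 / 3 for the rest
  aln <- protein_alignment(c(r1 = "AC", r2 = "AC"))
  h <- suppressWarnings(build_hmm(aln, "toy", weights = "uniform",
                                  background = rep(1 / 20, 20)))
  expect_equal(h$M, 2)
  expect_equal(unname(h$match_emissions[1, "A"]), (2 + 0.05) / 3)
  expect_equal(unname(h$match_emissions[1, "C"]), 0.05 / 3)
  expect_equal(unname(rowSums(h$match_emissions)), c(1, 1))
})

test_that("match columns are those with gap fraction below one half", {
  aln <- protein_alignment(c(r1 = "A-C", r2 = "AGC", r3 = "A-C"))
  h <- suppressWarnings(build_hmm(aln, "toy"))
  expect_equal(h$M, 2)  # middle column is 2/3 gaps -> insert column
  all_gap <- protein_alignment(c(r1 = "--", r2 = "--"))
  expect_error(suppressWarnings(build_hmm(all_gap, "bad")), "no match columns")
})

test_that("X residues contribute no emission counts", {
  with_x <- suppressWarnings(
    build_hmm(protein_alignment(c(r1 = "AC", r2 = "XC")), "x",
              weights = "uniform", background = rep(1 / 20, 20)))
  # column 1: one A counted, the X ignored -> (1 + 0.05) / (1 + 1)
  expect_equal(unname(with_x$match_emissions[1, "A"]), 1.05 / 2)
})

test_that("small seed alignments warn", {
  expect_warning(build_hmm(protein_alignment(c(r1 = "AC", r2 = "AC")), "toy"),
                 "fewer than 5")
})

test_that("Henikoff weights down-weight duplicated sequences and sum to n", {
  aln <- protein_alignment(c(a = "AAAA", b = "AAAA", c = "WCHP"))
  w <- henikoff_weights(aln)
  expect_equal(sum(w), 3)
  expect_lt(w[["a"]], w[["c"]])
  expect_equal(w[["a"]], w[["b"]])
})

test_that("profile validation catches malformed models", {
  aln <- protein_alignment(c(r1 = "MKTAY", r2 = "MKTAY", r3 = "MRTAY",
                             r4 = "MKCAY", r5 = "MKTAW"))
  h <- build_hmm(aln, "ok")
  expect_silent(validate_profile_hmm(h))
  bad <- h
  bad$match_emissions[1, ] <- bad$match_emissions[1, ] * 2
  expect_error(validate_profile_hmm(bad), "sum to 1")
  bad2 <- h
  bad2$transitions[h$M + 1, "MD"] <- 0.5
  expect_error(validate_profile_hmm(bad2), "final node|sum to 1")
})

scoring_fixture <- function() {
  fixture("scoring_fixture", function() {
    set.seed(61)
    root <- hmmforge:::random_protein(100)
    fam <- simulate_family(root, 10, 0.1, seed = 611, prefix = "f")
    aln <- progressive_align(fam)
    list(hmm = build_hmm(aln, "fam"), root = root, fam = fam)
  })
}

test_that("family members outscore random sequences, which can go negative", {
  fx <- scoring_fixture()
  fam_scores <- score_sequence(fx$hmm, fx$fam$residues)
  rand <- vapply(1:5, function(i) hmmforge:::random_protein(100), character(1))
  rand_scores <- score_sequence(fx$hmm, rand)
  expect_gt(min(fam_scores), 100)
  expect_lt(max(rand_scores), min(fam_scores))
  # no zero floor: a lone X emits at background everywhere, so its score is
  # exactly the entry cost log2(1/M), which is negative
  expect_equal(score_sequence(fx$hmm, "X"), -log2(fx$hmm$M))
  expect_lt(score_sequence(fx$hmm, "X"), 0)
})

test_that("X residues are score-neutral and scoring is length-local", {
  fx <- scoring_fixture()
  s <- fx$fam$residues[1]
  full <- score_sequence(fx$hmm, s)
  flanked <- score_sequence(fx$hmm, paste0("XXXXX", s, "XXXXX"))
  expect_lt(abs(full - flanked), 1e-6)
  half <- score_sequence(fx$hmm, substr(s, 1, 50))
  expect_lt(half, full)   # truncation loses score
  expect_gt(half, 0)
})

test_that("search_all returns deterministic ordering above the floor", {
  fx <- scoring_fixture()
  prots <- sequence_set(c("b", "a"), fx$fam$residues[1:2])
  hits <- search_all(list(fx$hmm), prots, floor = 0)
  expect_named(hits, c("hmm_name", "target_id", "bit_score"))
  expect_equal(hits$bit_score, sort(hits$bit_score, decreasing = TRUE))
  none <- search_all(list(fx$hmm), prots, floor = 1e9)
  expect_equal(nrow(none), 0)
})

test_that("the consensus sequence scores at least as high as family members", {
  fx <- scoring_fixture()
  cons <- consensus_sequence(fx$hmm)
  expect_equal(nchar(cons), fx$hmm$M)
  expect_gte(score_sequence(fx$hmm, cons),
             max(score_sequence(fx$hmm, fx$fam$residues)))
})
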