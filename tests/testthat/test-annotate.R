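# Classification tiers, best-hit resolution, normalization and summaries.

test_that("tier boundaries are inclusive at both cutoffs", {
  pair <- cutoff_pair(100, 80)
  expect_identical(classify_hit(100, pair), "confident")
  expect_identical(classify_hit(99.999, pair), "ambiguous")
  expect_identical(classify_hit(80, pair), "ambiguous")
  expect_identical(classify_hit(79.999, pair), "rejected")
})

test_that("tier is monotone in score for fixed cutoffs", {
  pair <- cutoff_pair(100, 80)
  rank <- c(rejected = 1, ambiguous = 2, confident = 3)
  tiers <- rank[classify_hit(seq(0, 200, by = 0.5), pair)]
  expect_true(all(diff(tiers) >= 0))
})

fake_db <- function() {
  aln <- protein_alignment(c(r1 = "MKTAY", r2 = "MKTAY", r3 = "MRTAY",
                             r4 = "MKCAY", r5 = "MKTAW"))
  list(H1 = attach_cutoffs(build_hmm(aln, "H1"), cutoff_pair(100, 80)),
       H2 = attach_cutoffs(build_hmm(aln, "H2"), cutoff_pair(50, 40)))
}

test_that("the highest-scoring confident HMM wins, ties break by name", {
  db <- fake_db()
  hits <- data.frame(hmm_name = c("H1", "H2"), target_id = "g",
                     bit_score = c(120, 60), stringsAsFactors = FALSE)
  rec <- assign_best(hits, db)
  expect_identical(rec$assigned_hmm, "H1")
  expect_identical(rec$tier, "confident")
  tie <- data.frame(hmm_name = c("H2", "H1"), target_id = "g",
                    bit_score = c(120, 120), stringsAsFactors = FALSE)
  expect_identical(assign_best(tie, db)$assigned_hmm, "H1")
})

test_that("ambiguous fallback and rejected records behave per contract", {
  db <- fake_db()
  amb <- data.frame(hmm_name = c("H1", "H2"), target_id = "g",
                    bit_score = c(90, 45), stringsAsFactors = FALSE)
  rec <- assign_best(amb, db)
  expect_identical(rec$tier, "ambiguous")
  expect_identical(rec$assigned_hmm, "H1")
  rej <- data.frame(hmm_name = c("H1", "H2"), target_id = "g",
                    bit_score = c(10, 5), stringsAsFactors = FALSE)
  rec2 <- assign_best(rej, db)
  expect_identical(rec2$tier, "rejected")
  expect_true(is.na(rec2$assigned_hmm))   # rejected carries no assignment
})

test_that("cutoff-mode annotation covers every gene exactly once", {
  sb <- small_build()
  genome <- simulate_genome(sb$bench, n_background = 30, seed = 2)
  recs <- annotate_sample(genome$proteins, sb$res$hmms)
  expect_equal(sort(recs$gene_id), sort(genome$proteins$id))
  expect_equal(anyDuplicated(recs$gene_id), 0)
  markers <- genome$truth$id[genome$truth$role == "marker"]
  expect_true(all(recs$tier[recs$gene_id %in% markers] == "confident"))
})

test_that("cutoff mode refuses models without cutoffs", {
  aln <- protein_alignment(c(r1 = "MKTAY", r2 = "MKTAY", r3 = "MRTAY",
                             r4 = "MKCAY", r5 = "MKTAW"))
  h <- build_hmm(aln, "bare")
  prots <- sequence_set("g1", "MKTAY")
  expect_error(annotate_sample(prots, list(h)), "cutoff")
  expect_silent(out <- annotate_sample(prots, list(h), mode = "evalue"))
})

test_that("evalue mode keeps one row per passing hit with the built-in
           estimate", {
  sb <- small_build()
  genome <- simulate_genome(sb$bench, n_background = 30, seed = 2)
  recs <- annotate_sample(genome$proteins, sb$res$hmms, mode = "evalue",
                          max_evalue = 1e-50)
  expect_named(recs, c("gene_id", "assigned_hmm", "bit_score", "evalue"))
  n <- nrow(genome$proteins)
  expect_equal(recs$evalue, n * 2^(-recs$bit_score))
  expect_true(all(recs$evalue <= 1e-50))
})

test_that("per-million normalization is exact and scale invariant", {
  expect_equal(normalize_counts(5, 2e6), 2.5)
  expect_equal(normalize_counts(0, 100), 0)
  expect_equal(normalize_counts(10, 1000), normalize_counts(20, 2000))
  expect_error(normalize_counts(5, 0), "positive")
})

test_that("summary matrix counts by tier and respects metadata", {
  recs <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    assigned_hmm = c("H1", "H1", "H2", NA),
    bit_score = c(120, 110, 60, 5),
    tier = c("confident", "ambiguous", "confident", "rejected"),
    stringsAsFactors = FALSE)
  md <- function_metadata(c("H1", "H2"), c("alkane", "aromatic"),
                          c("aerobic", "anaerobic"))
  tab <- summary_matrix(list(s1 = recs), md,
                        total_genes = c(s1 = 1e6))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$confident_count[tab$hmm == "H1"], 1)
  expect_equal(tab$ambiguous_count[tab$hmm == "H1"], 1)
  expect_equal(tab$rate_per_million[tab$hmm == "H2"], 1)
  expect_equal(sum(tab$confident_count), sum(recs$tier == "confident"))
  expect_error(summary_matrix(list(s1 = recs), md, hmm_names = c("H1", "H3")),
               "missing from metadata")
})
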