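# Multiple alignment, distance matrices, NJ trees and seed-clade extraction.

test_that("progressive alignment preserves ids, order and residues", {
  set.seed(31)
  root <- hmmforge:::random_protein(80)
  x <- sequence_set(c("s1", "s2", "s3"),
                    c(root, hmmforge:::mutate_protein(root, 0.1),
                      hmmforge:::mutate_protein(root, 0.1)))
  aln <- progressive_align(x)
  expect_s3_class(aln, "ProteinAlignment")
  expect_identical(names(aln), x$id)
  expect_identical(unname(vapply(aln, ungap, character(1))), x$residues)
})

test_that("single-sequence alignment is the sequence itself", {
  x <- sequence_set("only", "MKTAYIAKQR")
  aln <- progressive_align(x)
  expect_identical(unclass(aln), c(only = "MKTAYIAKQR"))
})

test_that("p-distances count mismatches over shared columns", {
  aln <- protein_alignment(c(a = "MKTA-", b = "MQSA-", c = "MK-AW"))
  d <- distance_matrix(aln)
  expect_equal(d["a", "b"], 2 / 4)
  expect_equal(d["a", "c"], 0 / 3)
  expect_equal(d["b", "c"], 1 / 3)
  expect_true(isSymmetric(d))
  bad <- protein_alignment(c(x = "MK--", y = "--AW"))
  expect_error(distance_matrix(bad), "share no aligned")
})

test_that("neighbor joining recovers an additive topology", {
  # ((a,b),(c,d)) with internal branch 3
  taxa <- c("a", "b", "c", "d")
  d <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  d["a", "b"] <- d["b", "a"] <- 2
  d["c", "d"] <- d["d", "c"] <- 2
  for (i in c("a", "b")) for (j in c("c", "d")) d[i, j] <- d[j, i] <- 5
  tr <- nj_tree(d)
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
  expect_true(all(tr$edge.length >= 0))
  expect_error(nj_tree(d[1:2, 1:2]), "3 taxa")
})

seed_clade_fixture <- function() {
  set.seed(41)
  root <- hmmforge:::random_protein(120)
  core_root <- hmmforge:::mutate_protein(root, 0.1)
  out_root <- hmmforge:::mutate_protein(root, 0.5)
  core <- vapply(1:6, function(i) hmmforge:::mutate_protein(core_root, 0.05),
                 character(1))
  outg <- vapply(1:3, function(i) hmmforge:::mutate_protein(out_root, 0.05),
                 character(1))
  members <- sequence_set(
    id = c(sprintf("core%d", 1:6), sprintf("out%d", 1:3)),
    residues = c(core, outg),
    evidence = c("verified", "verified", rep("unknown", 7)),
    function_label = c("FN", "FN", rep(NA, 7)))
  grp <- homologous_group("FN", members, c("core1", "core2"))
  tree <- nj_tree(distance_matrix(progressive_align(members)))
  list(group = grp, tree = tree)
}

test_that("seed clade is the MRCA clade of the verified archetypes", {
  fx <- seed_clade_fixture()
  seed <- extract_seed_clade(fx$tree, fx$group)
  expect_true(all(c("core1", "core2") %in% seed$ids))
  expect_false(any(startsWith(seed$ids, "out")))
  expect_false(seed$non_monophyletic_warning)
})

test_that("whole-tree clades carry the non-monophyletic warning", {
  set.seed(43)
  root <- hmmforge:::random_protein(100)
  members <- sequence_set(
    id = c("v1", "u1", "v2"),
    residues = c(root, hmmforge:::mutate_protein(root, 0.1),
                 hmmforge:::mutate_protein(root, 0.4)),
    evidence = c("verified", "unknown", "verified"),
    function_label = c("FN", NA, "FN"))
  grp <- homologous_group("FN", members, c("v1", "v2"))
  tree <- nj_tree(distance_matrix(progressive_align(members)))
  seed <- extract_seed_clade(tree, grp)
  expect_setequal(seed$ids, members$id)
  expect_true(seed$non_monophyletic_warning)
})

test_that("seed overrides replace the automatic clade but keep verified ids", {
  fx <- seed_clade_fixture()
  seed <- extract_seed_clade(fx$tree, fx$group,
                             override = c("out1", "core3"))
  expect_setequal(seed$ids, c("out1", "core3", "core1", "core2"))
  expect_error(extract_seed_clade(fx$tree, fx$group, override = "ghost"),
               "not in tree")
})

test_that("missing verified archetypes in the tree are an error", {
  fx <- seed_clade_fixture()
  pruned <- ape::drop.tip(fx$tree, "core1")
  expect_error(extract_seed_clade(pruned, fx$group), "missing from tree")
})
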