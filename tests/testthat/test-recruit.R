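# Homolog recruitment filters and recruit-set compaction.

make_recruit_fixture <- function() {
  set.seed(21)
  root <- hmmforge:::random_protein(200)
  arch <- sequence_set("arch1", root, evidence = "verified",
                       function_label = "FN")
  grp <- homologous_group("FN", arch, "arch1")
  homs <- vapply(1:6, function(i) hmmforge:::mutate_protein(root, 0.2),
                 character(1))
  short <- substr(hmmforge:::mutate_protein(root, 0.05), 1, 80)  # low coverage
  bg <- vapply(1:5, function(i) hmmforge:::random_protein(200), character(1))
  db <- sequence_set(c(sprintf("hom%02d", 1:6), "short1",
                       sprintf("bg%02d", 1:5)),
                     c(homs, short, bg))
  list(group = grp, db = db)
}

test_that("recruitment keeps homologs passing both filters and labels them", {
  fx <- make_recruit_fixture()
  out <- recruit_homologs(fx$group, fx$db)
  got <- setdiff(out$members$id, "arch1")
  expect_setequal(got, sprintf("hom%02d", 1:6))       # all true homologs
  expect_false(any(startsWith(got, "bg")))            # background rejected
  expect_false("short1" %in% got)                     # qcov < 0.70 rejected
  expect_true(all(out$members$evidence[out$members$id %in% got] == "recruited"))
  expect_true("arch1" %in% out$members$id)            # archetypes retained
})

test_that("coverage threshold is measured on the archetype (query)", {
  fx <- make_recruit_fixture()
  relaxed <- recruit_homologs(fx$group, fx$db, min_qcov = 0.3)
  expect_true("short1" %in% relaxed$members$id)
})

test_that("a custom search backend adapter is accepted and errors are wrapped", {
  fx <- make_recruit_fixture()
  backend <- function(group, database) {
    data.frame(query = "arch1", target = database$id,
               score = 100, qcov = 1.0,
               evalue = ifelse(startsWith(database$id, "hom"), 1e-10, 1),
               stringsAsFactors = FALSE)
  }
  out <- recruit_homologs(fx$group, fx$db, backend = backend)
  expect_setequal(setdiff(out$members$id, "arch1"), sprintf("hom%02d", 1:6))
  boom <- function(group, database) stop("backend down")
  expect_error(recruit_homologs(fx$group, fx$db, backend = boom),
               "search backend failed for group 'FN'")
})

test_that("compaction dereplicates and clusters, protecting archetypes", {
  base <- paste(rep("MKTAYIAKQR", 20), collapse = "")
  one_sub <- sub("T", "S", base)
  members <- sequence_set(
    id = c("arch1", "dup1", "near1", "far1"),
    residues = c(base, base, one_sub, hmmforge:::random_protein(200)),
    evidence = c("verified", "recruited", "recruited", "recruited"),
    function_label = c("FN", NA, NA, NA))
  grp <- homologous_group("FN", members, "arch1")
  out <- compact_recruits(grp, cluster_identity = 0.98)
  expect_true("arch1" %in% out$members$id)   # archetype survives
  expect_false("dup1" %in% out$members$id)   # exact duplicate dropped
  expect_false("near1" %in% out$members$id)  # >= 98% identical to arch1
  expect_true("far1" %in% out$members$id)
})

test_that("representative priority is verified > putative > recruited", {
  members <- sequence_set(
    id = c("r1", "p1", "v1"),
    residues = rep("MKTAYIAKQR", 3) ,
    evidence = c("recruited", "putative", "verified"),
    function_label = c(NA, "FN", "FN"))
  expect_identical(hmmforge:::pick_representative(c("r1", "p1", "v1"), members),
                   "v1")
  expect_identical(hmmforge:::pick_representative(c("r1", "p1"), members),
                   "p1")
})
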