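# Domain types and file formats: SequenceSet validation, FASTA with the
# evidence/function label dialect, HMMER3 ASCII profiles, newick, config.

test_that("sequence_set validates ids, residues and the evidence contract", {
  expect_s3_class(sequence_set("a", "ACDEF"), "SequenceSet")
  expect_error(sequence_set(c("a", "a"), c("AC", "AC")), "duplicate")
  expect_error(sequence_set("a", ""), "empty sequence")
  expect_error(sequence_set("a", "ACDEF1"), "non-amino-acid")
  expect_error(sequence_set("a", "ACDEF", evidence = "checked"), "evidence")
  expect_error(sequence_set("a", "ACDEF", evidence = "verified"),
               "function label")
  ok <- sequence_set("a", "ACDEF", evidence = "verified",
                     function_label = "AlkB")
  expect_identical(ok$function_label, "AlkB")
})

test_that("sequence_set strips stop characters and uppercases", {
  x <- sequence_set("a", "acdef*")
  expect_identical(x$residues, "ACDEF")
  expect_identical(sequence_set("b", "MKXT")$residues, "MKXT")  # X allowed
})

test_that("FASTA round-trips sequences and labels", {
  x <- sequence_set(id = c("v1", "u1"),
                    residues = c("MKTAYIAKQR", "WWCHHPGDEN"),
                    description = c("alkB homolog", ""),
                    evidence = c("verified", "unknown"),
                    function_label = c("AlkB", NA))
  f <- tempfile(fileext = ".faa")
  write_fasta(x, f)
  y <- read_fasta(f)
  expect_identical(y$id, x$id)
  expect_identical(y$residues, x$residues)
  expect_identical(y$evidence, x$evidence)
  expect_identical(y$function_label, x$function_label)
  expect_identical(y$description, x$description)
})

test_that("FASTA reader handles wrapping, empty files and missing files", {
  x <- sequence_set("long1", paste(rep("ACDEFGHIKL", 20), collapse = ""))
  f <- tempfile(fileext = ".faa")
  write_fasta(x, f, wrap = 17)
  expect_identical(read_fasta(f)$residues, x$residues)
  empty <- tempfile()
  file.create(empty)
  expect_equal(nrow(read_fasta(empty)), 0)
  expect_error(read_fasta(tempfile()), "no such file")
})

small_hmm <- function(name = "toy") {
  aln <- protein_alignment(c(r1 = "MKT", r2 = "MKT", r3 = "MRT", r4 = "LKT",
                             r5 = "MKC"))
  build_hmm(aln, name)
}

test_that("HMMER3 write/read round-trips models within 1e-5", {
  h <- attach_cutoffs(small_hmm(), cutoff_pair(100.0, 80.0))
  f <- tempfile(fileext = ".hmm")
  write_hmmer3(h, f)
  back <- read_hmmer3(f)
  expect_named(back, "toy")
  h2 <- back[["toy"]]
  expect_identical(h2$M, h$M)
  expect_lt(max(abs(h2$match_emissions - h$match_emissions)), 1e-5)
  expect_lt(max(abs(h2$insert_emissions - h$insert_emissions)), 1e-5)
  expect_lt(max(abs(h2$transitions - h$transitions)), 1e-5)
  expect_equal(h2$cutoffs$trusted, 100.0)
  expect_equal(h2$cutoffs$noise, 80.0)
})

test_that("HMMER3 reader maps header fields and handles multiple models", {
  hs <- list(attach_cutoffs(small_hmm("m1"), cutoff_pair(100.0, 80.0)),
             small_hmm("m2"))
  f <- tempfile(fileext = ".hmm")
  write_hmmer3(hs, f)
  back <- read_hmmer3(f)
  expect_named(back, c("m1", "m2"))
  expect_equal(back$m1$M, 3)            # LENG -> M
  expect_equal(back$m1$cutoffs$trusted, 100.0)  # TC line -> CutoffPair
  expect_equal(back$m1$cutoffs$noise, 80.0)     # NC line -> CutoffPair
  expect_null(back$m2$cutoffs)
})

test_that("HMMER3 reader rejects non-amino alphabets and truncated models", {
  f <- tempfile(fileext = ".hmm")
  write_hmmer3(small_hmm(), f)
  lines <- readLines(f)
  bad <- sub("^ALPH  amino", "ALPH  DNA", lines)
  writeLines(bad, f)
  expect_error(read_hmmer3(f), "alphabet")
  trunc <- lines[seq_len(length(lines) - 4)]  # cut mid-node, lose //
  writeLines(trunc, f)
  expect_error(read_hmmer3(f), "line")
})

test_that("empty model collection writes an empty file", {
  f <- tempfile(fileext = ".hmm")
  write_hmmer3(list(), f)
  expect_equal(file.size(f), 0)
})

test_that("newick trees round-trip", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, tr$tip.label)
})

test_that("run configuration reads YAML over defaults and validates", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(archetypes = "a.faa", database = "d.faa",
                        out_dir = "o", min_qcov = 0.5), f)
  cfg <- read_config(f)
  expect_equal(cfg$min_qcov, 0.5)
  expect_equal(cfg$max_evalue, 1e-4)  # default preserved
  expect_error(run_build(list(database = "d.faa", out_dir = "o")),
               "config error")
  expect_error(run_build(list(archetypes = tempfile(), database = tempfile(),
                              out_dir = tempfile())), "config error")
})

test_that("function_metadata validates its enums", {
  md <- function_metadata("AlkB", "alkane", "aerobic")
  expect_s3_class(md, "FunctionMetadata")
  expect_error(function_metadata("A", "plastic", "aerobic"), "substrate")
  expect_error(function_metadata(c("A", "A"), "alkane", "aerobic"),
               "duplicate")
})
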