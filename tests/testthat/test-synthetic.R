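# Seeded benchmark generator.

test_that("benchmark_spec validates divergences and counts", {
  expect_s3_class(benchmark_spec(), "BenchmarkSpec")
  expect_error(benchmark_spec(decoy_divergence = 0.1,
                              family_divergence = 0.2), "exceed")
  expect_error(benchmark_spec(n_functions = 0), "n_functions")
})

test_that("zero divergence copies the root; same seed reproduces", {
  root <- hmmforge:::random_protein(50)
  fam <- simulate_family(root, 5, 0, seed = 1)
  expect_true(all(fam$residues == root))
  a <- simulate_family(root, 5, 0.2, seed = 9)
  b <- simulate_family(root, 5, 0.2, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, simulate_family(root, 5, 0.2, seed = 10)))
})

test_that("mean pairwise identity decreases across a divergence grid", {
  root <- hmmforge:::random_protein(150)
  mean_ident <- function(div) {
    fam <- simulate_family(root, 20, div, seed = 77)
    pairs <- utils::combn(seq_len(10), 2)
    mean(apply(pairs, 2, function(p)
      percent_identity(fam$residues[p[1]], fam$residues[p[2]])))
  }
  idents <- vapply(c(0.05, 0.2, 0.5), mean_ident, numeric(1))
  expect_true(all(diff(idents) < 0))
})

test_that("make_benchmark emits labeled archetypes, relatives, decoys and
           a coherent truth table", {
  spec <- benchmark_spec(n_functions = 3, seqs_per_family = 10,
                         sequence_length = 100, rng_seed = 7)
  b <- make_benchmark(spec)
  expect_equal(nrow(b$archetypes), 3 * 4)       # 2 verified + 2 putative each
  expect_equal(sum(b$archetypes$evidence == "verified"), 6)
  expect_setequal(unique(b$archetypes$function_label),
                  c("FUN1", "FUN2", "FUN3"))
  expect_setequal(b$truth$id, b$database$id)
  expect_setequal(unique(b$truth$role),
                  c("verified", "putative", "homolog", "relative", "decoy",
                    "background"))
  validate_sequence_set(b$database)
  validate_sequence_set(b$archetypes)
})

test_that("decoys are less similar to function 1 than family members are", {
  spec <- benchmark_spec(n_functions = 1, seqs_per_family = 8,
                         sequence_length = 150, rng_seed = 3)
  b <- make_benchmark(spec)
  fam <- b$database[b$truth$family == "FUN1" & b$truth$role != "relative", ]
  dec <- b$database[b$truth$family == "DECOY", ]
  within <- percent_identity(fam$residues[1], fam$residues[2])
  cross <- max(vapply(dec$residues[1:4], function(d)
    percent_identity(fam$residues[1], d), numeric(1)))
  expect_gt(within, cross)
})

test_that("generation is deterministic and leaves the global RNG untouched", {
  set.seed(123)
  before <- .Random.seed
  b1 <- make_benchmark(benchmark_spec(n_functions = 1, seqs_per_family = 5,
                                      sequence_length = 60, rng_seed = 4))
  expect_identical(.Random.seed, before)
  b2 <- make_benchmark(benchmark_spec(n_functions = 1, seqs_per_family = 5,
                                      sequence_length = 60, rng_seed = 4))
  expect_identical(b1, b2)
})

test_that("simulated genomes plant verified archetype copies by default", {
  spec <- benchmark_spec(n_functions = 2, seqs_per_family = 5,
                         sequence_length = 80, rng_seed = 5)
  b <- make_benchmark(spec)
  g <- simulate_genome(b, n_background = 10, seed = 1)
  expect_equal(nrow(g$proteins), 2 + 1 + 10)
  markers <- g$proteins[startsWith(g$proteins$id, "marker"), ]
  ver <- b$archetypes[b$archetypes$evidence == "verified", ]
  expect_true(all(markers$residues %in% ver$residues))
})

test_that("benchmarks are written as FASTA + truth + spec", {
  spec <- benchmark_spec(n_functions = 1, seqs_per_family = 5,
                         sequence_length = 60, rng_seed = 6)
  b <- make_benchmark(spec)
  dir <- tempfile("bench")
  write_benchmark(b, dir)
  expect_true(all(file.exists(file.path(dir, c("archetypes.faa",
                                               "database.faa", "truth.tsv",
                                               "spec.yaml")))))
  back <- read_fasta(file.path(dir, "archetypes.faa"))
  expect_identical(back$residues, b$archetypes$residues)
  expect_identical(back$evidence, b$archetypes$evidence)
})
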