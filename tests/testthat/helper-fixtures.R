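# Shared fixtures. Expensive pipeline runs are built lazily, once per test
# session, and reused by the tests that need them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# tiny deterministic protein strings
tiny_seqs <- function() c(
  s1 = "MKTAYIAKQR",
  s2 = "MKTAYIAKQR",
  s3 = "MKTAYLAKQR",
  s4 = "WWCHHPGDEN"
)

# a small benchmark + full build, shared by module tests (NOT by acceptance
# tests, which use the spec-scale settings)
small_build <- function() {
  fixture("small_build", function() {
    spec <- benchmark_spec(n_functions = 2, seqs_per_family = 10,
                           sequence_length = 120, rng_seed = 11)
    bench <- make_benchmark(spec)
    dir <- tempfile("smallbuild")
    write_benchmark(bench, dir)
    res <- run_build(list(archetypes = file.path(dir, "archetypes.faa"),
                          database = file.path(dir, "database.faa"),
                          out_dir = file.path(dir, "build")))
    list(bench = bench, dir = dir, res = res)
  })
}

# full spec-scale benchmark build at the parameter-recovery settings
# (shared by the acceptance blocks and the HMMER-compatibility check)
recovery_build <- function() {
  fixture("recovery_build", function() {
    spec <- benchmark_spec(n_functions = 3, seqs_per_family = 50,
                           family_divergence = 0.15, decoy_divergence = 0.6,
                           rng_seed = 7)
    bench <- make_benchmark(spec)
    dir <- tempfile("recovery")
    write_benchmark(bench, dir)
    res <- run_build(list(archetypes = file.path(dir, "archetypes.faa"),
                          database = file.path(dir, "database.faa"),
                          out_dir = file.path(dir, "build")))
    genome <- simulate_genome(bench, n_background = 500, seed = 7)
    list(bench = bench, dir = dir, res = res, genome = genome)
  })
}

# spec-scale benchmark build at the generator defaults (used by the
# specificity-emulation and truncation tests)
default_build <- function() {
  fixture("default_build", function() {
    bench <- make_benchmark(benchmark_spec())
    dir <- tempfile("default")
    write_benchmark(bench, dir)
    res <- run_build(list(archetypes = file.path(dir, "archetypes.faa"),
                          database = file.path(dir, "database.faa"),
                          out_dir = file.path(dir, "build")))
    genome <- simulate_genome(bench, n_background = 500, seed = 1)
    list(bench = bench, dir = dir, res = res, genome = genome)
  })
}
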