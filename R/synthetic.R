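# Seeded benchmark generator: divergent protein families descended from a
# common profile, a confounding paralog family sharing ancestry with the
# first true family (the glycyl-radical-enzyme / pyruvate-formate-lyase
# situation), and a background proteome. All randomness flows from the single
# spec seed; the global RNG state is left untouched.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Benchmark specification
#'
#' Defines the statistical structure of a synthetic benchmark: a set of
#' function families evolved from random root profiles, a confounding decoy
#' family branching off the first family, and a background proteome.
#' Divergences are expected substitutions per site measured from the family
#' root to each member.
#'
#' @param n_functions number of true marker-gene families (default 3).
#' @param seqs_per_family homologs per family (default 50).
#' @param family_divergence root-to-member substitutions/site within a family
#'   (default 0.15).
#' @param decoy_divergence substitutions/site between the first family's root
#'   and the decoy family's root; must exceed `family_divergence` (default
#'   0.35, a recent paralog).
#' @param background_size number of unrelated background proteins (default
#'   500).
#' @param sequence_length protein length in residues (default 400, a typical
#'   catalytic-subunit length).
#' @param rng_seed integer seed driving all randomness.
#' @return an object of class `BenchmarkSpec`.
#' @export
benchmark_spec <- function(n_functions = 3, seqs_per_family = 50,
                           family_divergence = 0.15, decoy_divergence = 0.35,
                           background_size = 500, sequence_length = 400,
                           rng_seed = 1) {
  stopifnot(n_functions >= 1, seqs_per_family >= 1, background_size >= 1,
            sequence_length >= 1, family_divergence >= 0,
            decoy_divergence >= 0)
  if (decoy_divergence <= family_divergence)
    stop("decoy_divergence must exceed family_divergence")
  structure(list(n_functions = as.integer(n_functions),
                 seqs_per_family = as.integer(seqs_per_family),
                 family_divergence = family_divergence,
                 decoy_divergence = decoy_divergence,
                 background_size = as.integer(background_size),
                 sequence_length = as.integer(sequence_length),
                 rng_seed = as.integer(rng_seed)),
            class = "BenchmarkSpec")
}

random_protein <- function(length, bg = background_frequencies()) {
  paste(sample(AMINO_ALPHABET, length, replace = TRUE, prob = bg),
        collapse = "")
}

# Poisson(divergence * length) substitutions, replacements drawn from the
# background excluding the current residue
mutate_protein <- function(seq, divergence, bg = background_frequencies()) {
  if (divergence <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n_sub <- stats::rpois(1, divergence * length(chars))
  if (n_sub > 0) {
    pos <- sample.int(length(chars), min(n_sub, length(chars)))
    repl <- sample(AMINO_ALPHABET, length(pos), replace = TRUE, prob = bg)
    same <- repl == chars[pos]
    while (any(same)) {  # substitutions must change the residue
      repl[same] <- sample(AMINO_ALPHABET, sum(same), replace = TRUE, prob = bg)
      same <- repl == chars[pos]
    }
    chars[pos] <- repl
  }
  paste(chars, collapse = "")
}

#' Simulate a protein family from a root sequence
#'
#' Each member evolves independently from the root by Poisson(divergence x
#' length) substitutions drawn from the background composition; deterministic
#' under a fixed seed.
#'
#' @param root_profile root protein sequence string.
#' @param n family size.
#' @param divergence expected substitutions/site from root to member.
#' @param seed integer seed.
#' @param prefix id prefix for the generated records.
#' @return a `SequenceSet` of `n` members.
#' @export
simulate_family <- function(root_profile, n, divergence, seed,
                            prefix = "fam") {
  with_seed(seed, {
    sequence_set(id = sprintf("%s_%03d", prefix, seq_len(n)),
                 residues = vapply(seq_len(n),
                                   function(i) mutate_protein(root_profile,
                                                              divergence),
                                   character(1)))
  })
}

# a family with two deep subclades (experimentally verified references come
# from distant taxa, so the curated archetypes span the function clade)
structured_family <- function(root, n, divergence, prefix) {
  half <- divergence / 2
  sub1 <- mutate_protein(root, half)
  sub2 <- mutate_protein(root, half)
  n1 <- ceiling(n / 2); n2 <- n - n1
  members <- sequence_set(
    id = sprintf("%s_%03d", prefix, seq_len(n)),
    residues = c(vapply(seq_len(n1), function(i) mutate_protein(sub1, half),
                        character(1)),
                 if (n2 > 0) vapply(seq_len(n2),
                                    function(i) mutate_protein(sub2, half),
                                    character(1))))
  attr(members, "subclade") <- rep(c(1L, 2L), c(n1, n2))
  members
}

#' Generate a full synthetic benchmark
#'
#' Per function: 2 verified + 2 putative archetypes and `seqs_per_family`
#' homologs, drawn from a family with two deep subclades so the verified
#' archetypes span the clade (one per subclade), plus a small distant-relatives
#' subfamily (outgroup ancestor at 1.5 x `family_divergence` from the family
#' root) supplying each group's phylogenetically related off-target
#' sequences — the recruits that sit outside the seed clade and anchor the
#' noise cutoff. One decoy family shares ancestry with function 1 (root at
#' `decoy_divergence` from function 1's root) and a different function. The
#' homolog database pools all family members, the relatives, the decoys and a
#' background proteome. A truth table maps every sequence to its family.
#'
#' @param spec a [benchmark_spec()].
#' @return list with `archetypes` (labeled `SequenceSet`), `database`
#'   (`SequenceSet`), `truth` (data frame id/family/role), `roots` (named
#'   root sequences incl. the decoy), and `spec`.
#' @export
make_benchmark <- function(spec) {
  stopifnot(inherits(spec, "BenchmarkSpec"))
  with_seed(spec$rng_seed, {
    fnames <- sprintf("FUN%d", seq_len(spec$n_functions))
    roots <- stats::setNames(
      vapply(fnames, function(f) random_protein(spec$sequence_length),
             character(1)), fnames)
    archetypes <- NULL
    database <- NULL
    truth <- NULL
    for (f in fnames) {
      fam <- structured_family(roots[[f]], spec$seqs_per_family + 4,
                               spec$family_divergence, prefix = f)
      sub <- attr(fam, "subclade")
      # archetypes: first two members of each subclade (verified, putative)
      a1 <- which(sub == 1)[1:2]; a2 <- which(sub == 2)[1:2]
      fam$evidence[c(a1[1], a2[1])] <- "verified"
      fam$evidence[c(a1[2], a2[2])] <- "putative"
      fam$function_label[c(a1, a2)] <- f
      arch <- fam[fam$evidence != "unknown", , drop = FALSE]
      class(arch) <- c("SequenceSet", "data.frame")
      archetypes <- if (is.null(archetypes)) arch else rbind(archetypes, arch)
      # distant relatives: same family, basal to the seed clade (off-targets)
      n_rel <- max(4L, round(spec$seqs_per_family / 5))
      rel_root <- mutate_protein(roots[[f]], 1.5 * spec$family_divergence)
      relatives <- sequence_set(
        id = sprintf("%s_rel_%03d", f, seq_len(n_rel)),
        residues = vapply(seq_len(n_rel),
                          function(i) mutate_protein(rel_root,
                                                     spec$family_divergence / 2),
                          character(1)))
      database <- if (is.null(database)) fam else rbind(database, fam)
      database <- rbind(database, relatives)
      truth <- rbind(truth,
                     data.frame(id = fam$id, family = f,
                                role = ifelse(fam$evidence == "unknown",
                                              "homolog", fam$evidence),
                                stringsAsFactors = FALSE),
                     data.frame(id = relatives$id, family = f,
                                role = "relative", stringsAsFactors = FALSE))
    }
    decoy_root <- mutate_protein(roots[["FUN1"]], spec$decoy_divergence)
    decoys <- structured_family(decoy_root, spec$seqs_per_family,
                                spec$family_divergence, prefix = "DECOY")
    truth <- rbind(truth, data.frame(id = decoys$id, family = "DECOY",
                                     role = "decoy", stringsAsFactors = FALSE))
    background <- sequence_set(
      id = sprintf("BG_%04d", seq_len(spec$background_size)),
      residues = vapply(seq_len(spec$background_size),
                        function(i) random_protein(spec$sequence_length),
                        character(1)))
    truth <- rbind(truth, data.frame(id = background$id, family = "BACKGROUND",
                                     role = "background",
                                     stringsAsFactors = FALSE))
    database <- rbind(database, decoys, background)
    class(database) <- c("SequenceSet", "data.frame")
    class(archetypes) <- c("SequenceSet", "data.frame")
    roots <- c(roots, DECOY = decoy_root)
    list(archetypes = archetypes, database = database, truth = truth,
         roots = roots, spec = spec)
  })
}

#' Simulate a held-out genome carrying planted marker genes
#'
#' Plants one marker gene per function (by default an exact copy of a
#' verified archetype, mirroring validation against genomes of the organisms
#' the references came from), one fresh decoy-family gene, and unrelated
#' background proteins.
#'
#' @param benchmark output of [make_benchmark()].
#' @param n_background background proteins (default 500).
#' @param marker_divergence substitutions/site applied to the planted markers
#'   (default 0: exact archetype copies).
#' @param seed integer seed.
#' @return list with `proteins` (a `SequenceSet`) and `truth` (id/family/role).
#' @export
simulate_genome <- function(benchmark, n_background = 500,
                            marker_divergence = 0, seed = 1) {
  spec <- benchmark$spec
  with_seed(seed, {
    arch <- benchmark$archetypes
    fnames <- sprintf("FUN%d", seq_len(spec$n_functions))
    markers <- vapply(fnames, function(f) {
      src <- arch[arch$function_label == f & arch$evidence == "verified", ]
      mutate_protein(src$residues[1], marker_divergence)
    }, character(1))
    decoy <- mutate_protein(benchmark$roots[["DECOY"]],
                            spec$family_divergence)
    bg <- vapply(seq_len(n_background),
                 function(i) random_protein(spec$sequence_length),
                 character(1))
    proteins <- sequence_set(
      id = c(sprintf("marker_%s", fnames), "decoy_gene",
             sprintf("bg_%04d", seq_len(n_background))),
      residues = c(markers, decoy, bg))
    truth <- data.frame(
      id = proteins$id,
      family = c(fnames, "DECOY", rep("BACKGROUND", n_background)),
      role = c(rep("marker", length(fnames)), "decoy",
               rep("background", n_background)),
      stringsAsFactors = FALSE)
    list(proteins = proteins, truth = truth)
  })
}

#' Write a benchmark to disk (FASTA + truth TSV + spec YAML)
#'
#' @param benchmark output of [make_benchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(benchmark$archetypes, file.path(dir, "archetypes.faa"))
  write_fasta(benchmark$database, file.path(dir, "database.faa"))
  write_tsv_report(benchmark$truth, file.path(dir, "truth.tsv"))
  yaml::write_yaml(unclass(benchmark$spec), file.path(dir, "spec.yaml"))
  invisible(dir)
}
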