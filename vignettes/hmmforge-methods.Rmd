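---
title: "Methods: curated profile HMMs for marker-gene annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curated profile HMMs for marker-gene annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## Why curated models

Detecting a metabolic capability such as hydrocarbon degradation in a genome
or metagenome is usually done by searching predicted proteins against profile
hidden Markov models (HMMs) of marker genes. Generic family models are too
broad for this: many marker genes sit inside large superfamilies whose other
members carry out different chemistry, so a raw family hit says "homolog", not
"this function". `hmmforge` implements the opposite philosophy: each model is
*phylogenetically curated* so that it is anchored on experimentally verified
sequences, and each model carries bit-score cutoffs calibrated against its own
close-but-functionally-distinct relatives.

The build workflow is:

1. **Archetype grouping.** Curated reference proteins (labeled
   `verified` or `putative`, each with a function label) are merged into
   homologous groups when a local alignment reaches at least 20% identity
   *and* a Karlin-Altschul E-value of at most 1e-4. The identity threshold
   alone is not meaningful for local alignments — a Smith-Waterman alignment
   of two unrelated proteins happily reports a short high-identity segment —
   so the significance filter is what actually separates homologs from chance
   similarity, exactly as in a `blastp`-style search.
2. **Homolog recruitment.** Each group is used to query a large homolog
   database; hits are kept when query coverage is at least 0.70 and the
   E-value at most 1e-4. Coverage is measured on the query (the archetype)
   so that fragments cannot recruit through a short conserved core.
3. **Dereplication and clustering.** Exact duplicates are removed, then
   sequences are clustered greedily at 98% identity (longest-first centroid
   selection, first-matching-centroid assignment), keeping one representative
   per cluster. Verified archetypes are always protected from removal.
4. **Tree-based seed curation.** The group is aligned (`mafft`), a
   neighbor-joining tree is built from p-distances, midpoint rooted, and the
   smallest clade containing all verified archetypes is extracted as the seed
   set. Everything outside that clade — the near-miss homologs — is kept
   aside as the *off-target* set for calibration.
5. **Nested pruning for oversized groups.** When a group exceeds 5,000
   members a full tree is impractical, so the group walks an identity ladder
   (0.50, 0.70, 0.90, 0.98): cluster at the rung, build a tree over cluster
   representatives, keep only clusters inside the archetype clade, re-expand,
   and move to the next rung until the group fits. Verified archetypes are
   retained unconditionally; if even the last rung cannot reduce the group
   below the cap, the seed is returned with an `oversize_warning`.
6. **Model construction.** The seed alignment becomes a profile HMM:
   alignment columns with gap fraction below one half are match states;
   emissions are Henikoff position-based sequence weights plus background
   pseudocounts; transitions get +1 pseudocounts. Models are read and written
   in the HMMER3 ASCII format so they interoperate with `hmmsearch`.
7. **Cutoff calibration.** Every group member is scored against the model.
   The *trusted* cutoff is the minimum score of a verified archetype; the
   *noise* cutoff is the maximum off-target score plus 0.1 bits. If no
   off-targets exist, noise collapses onto trusted; if the distributions
   overlap, both cutoffs collapse onto trusted and the model is flagged
   `overlap_conflict` for manual review.

## Annotation semantics

Scoring uses a local Viterbi algorithm in log2-odds bits: uniform entry into
any match state (cost `log2(1/M)`), free exit from any match state, no zero
floor (an unrelated protein scores negative), and `X` residues score zero
(background). A gene at or above the trusted cutoff is `confident`; at or
above noise but below trusted, `ambiguous`; below noise, `rejected`. Both
boundaries are inclusive. A gene hitting several models is assigned to the
highest-scoring one, with lexicographic model-name tie-breaking so reruns are
bit-identical. Metagenome counts are normalized per million predicted genes
so samples of different depth are comparable.

An alternative `evalue` mode reproduces what an uncalibrated screen would do:
keep every hit with estimated E-value at most 1e-50, where the E-value of a
bit score `S` against `n` target sequences is `n * 2^(-S)`. This mode is
deliberately included as a foil — it finds everything the calibrated mode
finds, plus spurious deep-homology hits — and is how the package demonstrates
why per-model cutoffs are worth the curation effort.

## The synthetic benchmark

Because no real curated reference set can ship inside a text-only package,
`hmmforge` includes a seeded generator (`make_benchmark()`) that produces the
full input ecosystem: archetypes, a homolog database, and ground truth.

* Each function family grows from a random root protein (default length 400,
  a typical enzyme length) with two deep subclades; the two verified
  archetypes are drawn one per subclade, so their most recent common ancestor
  is the family root and the extracted seed clade is the whole family —
  mirroring real curation, where verified references come from distant taxa.
* Each family also gets a small *distant-relatives* outgroup: an ancestor at
  1.5 times the family divergence, populated with `max(4, n/5)` members.
  These are recruitable homologs that fall outside the seed clade, so every
  model has a non-empty off-target partition and a meaningful noise cutoff.
  Without them, calibration would collapse `noise = trusted` for families
  that happen to recruit nothing foreign.
* A decoy family diverges from function 1's root at `decoy_divergence`
  (default 0.35) — close enough to be recruited as deep homologs, far enough
  to be functionally distinct.
* Evolution is substitution-only (no indels). This is the generator's main
  simplification: real families have length variation, which mafft and the
  match-column rule handle, but which would make ground-truth identity
  bookkeeping much less crisp. The pipeline itself does not assume equal
  lengths anywhere.
* All randomness flows through `with_seed()`, which saves and restores the
  global RNG state, so generation is reproducible and side-effect free.

Held-out genomes (`simulate_genome()`) plant one exact verified-archetype
copy per function plus a fresh decoy gene among hundreds of random background
proteins, emulating annotation of a genome from one of the source organisms.

## Numerical choices

* Alignments use BLOSUM62 with affine gaps (open 11, extend 1), the standard
  protein-homology parameterization; a gap of length L costs `open + L *
  extend`. Traceback ties break diagonal > up > left, deterministically.
* Pairwise identity is counted over aligned columns excluding terminal-gap
  overhang (so a domain insertion does not dilute identity), with an optional
  shorter-sequence denominator matching common clustering-tool semantics.
* Karlin-Altschul parameters (lambda 0.267, K 0.041, the gapped-BLOSUM62
  values) are configuration constants, not fitted; the filters that use them
  only require monotonicity in score, so their absolute calibration is not
  load-bearing.
* Profile files store negative natural logs at five decimals; on read, rows
  are renormalized so the in-memory invariant (rows sum to 1) is exact and
  round-trips are stable.
* The dynamic-programming kernels are in C++ with reusable workspaces; the
  `12,000 -> 5,000` pruning problem (tens of thousands of 400-residue
  alignments) completes in under two minutes.

All correctness-critical kernels are tested against exhaustive enumeration
oracles — every alignment path and every Viterbi state path on tiny instances
— rather than against a second dynamic-programming implementation, so
agreement is not explainable by a shared bug. Bit scores are additionally
cross-checked against HMMER's `hmmsearch` for rank agreement.

## Limitations

* Substitution-only synthetic data never exercises insert states with real
  indel structure; insert-state parameters are tested arithmetically instead.
* The Viterbi score is single-domain local; HMMER's full-sequence score sums
  multiple domains and models flanking residues explicitly, so absolute bits
  differ slightly (ranking agrees).
* The E-value model for HMM hits is the simple `n * 2^(-S)` bound, not a
  fitted Gumbel; it is used for the screening foil, not for calibration.
* Greedy clustering is order-dependent by design (it reproduces the
  `cluster_fast` semantics of sorting by decreasing length); it is not a
  globally optimal clustering.

## A complete run

```{r example}
library(hmmforge)

bench <- make_benchmark(benchmark_spec(rng_seed = 7))
dir <- tempfile("demo")
write_benchmark(bench, dir)

res <- run_build(list(
  archetypes = file.path(dir, "archetypes.faa"),
  database   = file.path(dir, "database.faa"),
  out_dir    = file.path(dir, "build")))

genome <- simulate_genome(bench, n_background = 500, seed = 1)
recs <- annotate_sample(genome$proteins, res$hmms)
table(recs$tier)
```
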