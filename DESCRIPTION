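Package: hmmforge
Title: Phylogenetically Curated Profile HMM Construction and Marker-Gene
    Annotation of Genomes and Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds marker-gene profile hidden Markov model (HMM) databases
    from curated archetype protein sequences and a homolog database, and
    annotates genomes and metagenomes with them. Archetypes are grouped into
    homologous groups by amino-acid identity, expanded by a coverage- and
    E-value-filtered homology search, dereplicated and clustered, and reduced
    to function-specific seed sets by neighbor-joining trees and monophyletic
    clade extraction, with a nested clustering/pruning ladder for oversized
    groups. Each seed alignment is turned into a profile HMM with trusted and
    noise bit-score cutoffs calibrated from the score distributions of
    experimentally verified versus off-target sequences. Annotation classifies
    hits into confident/ambiguous/rejected tiers, resolves genes hitting
    multiple HMMs to the highest-scoring model, and normalizes metagenome
    counts per million predicted genes. Includes a seeded synthetic benchmark
    generator, HMMER3 ASCII profile input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
SystemRequirements: mafft (multiple sequence alignment backend); HMMER3
    (optional external scoring engine cross-checks)
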