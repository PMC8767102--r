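# Multiple alignment (mafft backend), p-distance matrices, neighbor-joining
# trees and extraction of the monophyletic seed clade around the
# experimentally verified archetypes.

#' Multiple sequence alignment of a set of protein records
#'
#' Runs mafft (default progressive FFT-NS-2 mode, single thread, deterministic
#' column order) on the records and returns the alignment. A single record
#' aligns to itself ungapped.
#'
#' @param records a `SequenceSet` (>= 1 record).
#' @param mafft_args extra command-line arguments for mafft.
#' @return a [protein_alignment()] with rows in input order.
#' @export
progressive_align <- function(records, mafft_args = character()) {
  validate_sequence_set(records)
  if (nrow(records) == 0) stop("cannot align an empty set")
  if (nrow(records) == 1)
    return(protein_alignment(stats::setNames(records$residues, records$id)))
  if (!nzchar(Sys.which("mafft")))
    stop("mafft not found on PATH (required multiple-alignment backend)")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)))
  plain <- records
  plain$description <- ""; plain$evidence <- "unknown"
  plain$function_label <- NA_character_
  write_fasta(plain, fin)
  status <- suppressWarnings(
    system2("mafft", c("--quiet", "--thread", "1", "--anysymbol", mafft_args,
                       fin), stdout = fout, stderr = FALSE))
  if (status != 0) stop("mafft failed with exit status ", status)
  aln <- read_alignment(fout)
  # mafft preserves input order; keep ids aligned with the records
  aln <- aln[match(records$id, names(aln))]
  if (anyNA(names(aln))) stop("mafft dropped sequences from the alignment")
  protein_alignment(aln)
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i, j)` = mismatches / shared non-gap columns; zero on the diagonal and
#' symmetric. A pair sharing no aligned columns is an error.
#'
#' @param alignment a `ProteinAlignment` with >= 2 rows.
#' @return symmetric numeric matrix with row/column names.
#' @export
distance_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "ProteinAlignment"))
  if (length(alignment) < 2) stop("need at least 2 rows")
  d <- tryCatch(cpp_pdist(unclass(alignment)), error = function(e) {
    idx <- as.integer(regmatches(conditionMessage(e),
                                 gregexpr("[0-9]+", conditionMessage(e)))[[1]])
    if (length(idx) >= 2)
      stop("rows '", names(alignment)[idx[1]], "' and '",
           names(alignment)[idx[2]], "' share no aligned columns")
    stop(e)
  })
  dimnames(d) <- list(names(alignment), names(alignment))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining; negative branch lengths are clamped
#' to zero. Consistent: additive distances recover their generating topology.
#'
#' @param distmat symmetric distance matrix with >= 3 taxa and dimnames.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(distmat) {
  stopifnot(is.matrix(distmat))
  if (nrow(distmat) < 3) stop("need at least 3 taxa")
  if (!isSymmetric(unname(distmat), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tree <- ape::nj(distmat)
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Extract the seed clade containing the verified archetypes
#'
#' Roots the tree by midpoint, then returns all leaves under the most recent
#' common ancestor of the group's verified archetypes. When that clade spans
#' the whole tree the full leaf set is returned with a
#' `non_monophyletic_warning` flag (the analogue of falling back to a broader
#' function-specific seed set). An optional leaf-list override replaces the
#' automatic choice entirely.
#'
#' @param tree an `ape::phylo` whose tips include every verified archetype of
#'   the group.
#' @param group a `HomologousGroup`.
#' @param override optional character vector of leaf ids to use as the seed
#'   set instead of the MRCA clade.
#' @return list with `ids` (seed leaf labels) and `non_monophyletic_warning`
#'   (logical).
#' @export
extract_seed_clade <- function(tree, group, override = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(group, "HomologousGroup"))
  ver <- verified_ids(group)
  if (length(ver) == 0) stop("group '", group$name, "' has no verified archetype")
  miss <- setdiff(ver, tree$tip.label)
  if (length(miss) > 0)
    stop("verified archetype(s) missing from tree: ",
         paste(miss, collapse = ", "))
  if (!is.null(override)) {
    bad <- setdiff(override, tree$tip.label)
    if (length(bad) > 0)
      stop("override leaves not in tree: ", paste(bad, collapse = ", "))
    return(list(ids = union(override, ver), non_monophyletic_warning = FALSE))
  }
  if (length(tree$tip.label) == length(ver))
    return(list(ids = tree$tip.label, non_monophyletic_warning = TRUE))
  rooted <- phangorn::midpoint(tree)
  if (length(ver) == 1) {
    return(list(ids = ver, non_monophyletic_warning = FALSE))
  }
  mrca <- ape::getMRCA(rooted, ver)
  tips <- ape::extract.clade(rooted, mrca)$tip.label
  if (setequal(tips, rooted$tip.label))
    return(list(ids = rooted$tip.label, non_monophyletic_warning = TRUE))
  list(ids = tips, non_monophyletic_warning = FALSE)
}
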