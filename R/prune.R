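# Nested clustering + iterative phylogenetic-neighborhood pruning for
# homologous groups exceeding the size limit: cluster at the current identity
# rung, build a tree over cluster representatives (archetypes forced onto
# every tree), extract the seed clade of representatives, re-expand each
# selected representative to its full cluster membership, and repeat at the
# next rung until the group is small enough or the ladder tops out at 98%.

#' Pruning configuration
#'
#' @param max_group_size groups larger than this trigger the nested ladder
#'   (default 5000).
#' @param identity_ladder strictly increasing identity fractions ending at
#'   0.98 (default 0.50, 0.70, 0.90, 0.98).
#' @return an object of class `PruneConfig`.
#' @export
prune_config <- function(max_group_size = 5000,
                         identity_ladder = c(0.50, 0.70, 0.90, 0.98)) {
  if (max_group_size < 2) stop("max_group_size must be >= 2")
  if (any(diff(identity_ladder) <= 0))
    stop("identity ladder must be strictly increasing")
  if (utils::tail(identity_ladder, 1) != 0.98)
    stop("identity ladder must end at 0.98")
  structure(list(max_group_size = as.integer(max_group_size),
                 identity_ladder = identity_ladder), class = "PruneConfig")
}

subset_group <- function(group, ids) {
  members <- group$members[group$members$id %in% ids, , drop = FALSE]
  class(members) <- c("SequenceSet", "data.frame")
  homologous_group(group$name, members, group$archetype_ids)
}

align_tree_extract <- function(group, override = NULL, run_dir = NULL,
                               tag = "final") {
  aln <- progressive_align(group$members)
  seed <- if (length(aln) < 3) {
    list(ids = names(aln), non_monophyletic_warning = length(aln) > 1)
  } else {
    tree <- nj_tree(distance_matrix(aln))
    if (!is.null(run_dir))
      write_newick(tree, file.path(run_dir, paste0(group$name, "_", tag, ".nwk")))
    extract_seed_clade(tree, group, override = override)
  }
  seed
}

#' Reduce an oversized homologous group to a function-specific seed set
#'
#' When the group is within the size limit (or the ladder is exhausted) the
#' group is aligned, a neighbor-joining tree built, and the seed clade of the
#' verified archetypes extracted. Otherwise the group is clustered at the
#' current ladder rung, the clade extraction runs over cluster
#' representatives, selected representatives are re-expanded to their full
#' cluster membership, and the ladder advances (unconditionally, so the loop
#' terminates after at most `length(identity_ladder)` passes). Verified and
#' putative archetypes are never pruned.
#'
#' @param group a `HomologousGroup` with >= 1 verified archetype.
#' @param config a [prune_config()].
#' @param run_dir optional directory for per-iteration audit artifacts
#'   (cluster tables, newick trees, selected leaf lists).
#' @param override optional seed leaf list override passed to
#'   [extract_seed_clade()] in the final pass.
#' @return a `SequenceSet` of seed sequences (a subset of the group) with
#'   attributes `oversize_warning` and `non_monophyletic_warning`.
#' @export
nested_prune <- function(group, config = prune_config(), run_dir = NULL,
                         override = NULL) {
  stopifnot(inherits(group, "HomologousGroup"))
  if (length(verified_ids(group)) == 0)
    stop("group '", group$name, "' has no verified archetype")
  if (!is.null(run_dir) && !dir.exists(run_dir))
    dir.create(run_dir, recursive = TRUE)
  current <- group
  rungs <- config$identity_ladder
  iter <- 0
  while (nrow(current$members) > config$max_group_size && length(rungs) > 0) {
    iter <- iter + 1
    rung <- rungs[1]
    rungs <- rungs[-1]
    clusters <- greedy_cluster(current$members, rung)
    reps <- vapply(clusters,
                   function(cl) pick_representative(cl$member_ids,
                                                    current$members),
                   character(1))
    rep_ids <- unique(c(reps, group$archetype_ids))
    rep_group <- subset_group(current, rep_ids)
    if (!is.null(run_dir)) {
      utils::write.table(
        cluster_table(clusters),
        file.path(run_dir, sprintf("%s_iter%d_clusters.tsv", group$name, iter)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    seed <- align_tree_extract(rep_group, run_dir = run_dir,
                               tag = sprintf("iter%d", iter))
    if (!is.null(run_dir))
      writeLines(seed$ids, file.path(run_dir, sprintf("%s_iter%d_selected.txt",
                                                      group$name, iter)))
    # re-expand: each selected representative brings its full cluster back in
    selected_reps <- seed$ids
    expanded <- unlist(lapply(seq_along(clusters), function(i) {
      if (reps[i] %in% selected_reps) clusters[[i]]$member_ids else character()
    }))
    expanded <- unique(c(expanded, selected_reps, group$archetype_ids))
    current <- subset_group(current, expanded)
  }
  seed <- align_tree_extract(current, override = override, run_dir = run_dir)
  seed_ids <- unique(c(seed$ids, group$archetype_ids))
  out <- group$members[group$members$id %in% seed_ids, , drop = FALSE]
  class(out) <- c("SequenceSet", "data.frame")
  oversize <- nrow(out) > config$max_group_size
  if (oversize)
    warning("group '", group$name, "' still exceeds max_group_size after ",
            "exhausting the identity ladder")
  attr(out, "oversize_warning") <- oversize
  attr(out, "non_monophyletic_warning") <- isTRUE(seed$non_monophyletic_warning)
  out
}
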