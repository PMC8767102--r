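# Exact dereplication, greedy centroid clustering at an identity threshold
# (USEARCH cluster_fast-style semantics), and single-linkage grouping of
# archetypes into homologous groups.

new_cluster <- function(centroid_id, member_ids, threshold) {
  structure(list(centroid_id = centroid_id, member_ids = member_ids,
                 threshold = threshold), class = "Cluster")
}

#' Dereplicate identical sequences
#'
#' Two records share a cluster iff their residues are byte-identical; the
#' representative is the first member by input order.
#'
#' @param records a `SequenceSet`.
#' @return a list of `Cluster` objects (threshold 1.0).
#' @export
dereplicate <- function(records) {
  validate_sequence_set(records)
  if (nrow(records) == 0) return(list())
  key <- factor(records$residues, levels = unique(records$residues))
  lapply(split(records$id, key), function(ids)
    new_cluster(centroid_id = ids[1], member_ids = ids, threshold = 1.0))
}

#' Greedy centroid clustering at an identity threshold
#'
#' Records are processed in decreasing length order (ties broken by
#' lexicographic id); each joins the first existing centroid with global
#' percent identity at or above the threshold, else founds a new cluster.
#' The internal ordering makes the result invariant to input shuffling.
#'
#' @param records a `SequenceSet`.
#' @param threshold identity fraction in (0, 1].
#' @param matrix,gap_open,gap_extend alignment parameters (see
#'   [global_align()]).
#' @param identity_denominator see [global_align()].
#' @return a list of `Cluster` objects.
#' @export
greedy_cluster <- function(records, threshold, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1,
                           identity_denominator = c("columns", "shorter_seq")) {
  identity_denominator <- match.arg(identity_denominator)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  validate_sequence_set(records)
  if (nrow(records) == 0) return(list())
  ord <- order(-nchar(records$residues), records$id, method = "radix")
  recs <- records[ord, ]
  assign <- cpp_greedy_assign(recs$residues, threshold, matrix, gap_open,
                              gap_extend, identity_denominator == "shorter_seq")
  cents <- attr(assign, "centroids")
  lapply(seq_along(cents), function(c) {
    new_cluster(centroid_id = recs$id[cents[c]],
                member_ids = recs$id[assign == c], threshold = threshold)
  })
}

#' Cluster table in long format
#'
#' @param clusters list of `Cluster` objects.
#' @param records the clustered `SequenceSet` (to recompute member-centroid
#'   identities); optional.
#' @return data frame with cluster_id, centroid_id, member_id and, when
#'   `records` is given, identity_to_centroid.
#' @export
cluster_table <- function(clusters, records = NULL) {
  rows <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_id = i, centroid_id = cl$centroid_id,
               member_id = cl$member_ids, stringsAsFactors = FALSE)
  }))
  if (!is.null(records)) {
    res <- stats::setNames(records$residues, records$id)
    rows$identity_to_centroid <- mapply(function(c, m) {
      if (c == m) 1.0 else percent_identity(res[[m]], res[[c]])
    }, rows$centroid_id, rows$member_id)
  }
  rows
}

#' Group archetype sequences into homologous groups
#'
#' Single-linkage grouping over pairs with percent identity at or above the
#' threshold (default 20%, local blastp-like alignment gated by a local
#' E-value significance filter): loosely related
#' archetypes end up on one tree, and downstream phylogenetic pruning
#' separates functions. Archetypes linking to no one remain singleton groups.
#' Groups are named by their distinct function labels joined with `_`.
#'
#' @param archetypes a `SequenceSet` of verified/putative records with
#'   function labels.
#' @param threshold identity fraction (default 0.20).
#' @param grouping_alignment `"local"` (default, blastp-like) or `"global"`
#'   identity span. In local mode a pair additionally needs a significant
#'   local alignment (`max_link_evalue`), since local identity alone is high
#'   for any short matching segment.
#' @param max_link_evalue E-value gate for local-mode links (default 1e-4).
#' @param matrix,gap_open,gap_extend,ka_params alignment parameters.
#' @return a list of [homologous_group()] objects.
#' @export
group_archetypes <- function(archetypes, threshold = 0.20,
                             grouping_alignment = c("local", "global"),
                             max_link_evalue = 1e-4, matrix = blosum62(),
                             gap_open = 11, gap_extend = 1,
                             ka_params = karlin_altschul_params()) {
  grouping_alignment <- match.arg(grouping_alignment)
  validate_sequence_set(archetypes)
  if (!all(archetypes$evidence %in% c("verified", "putative")))
    stop("archetypes must carry evidence verified or putative")
  n <- nrow(archetypes)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        linked <- if (grouping_alignment == "local") {
          aln <- local_align(archetypes$residues[i], archetypes$residues[j],
                             matrix, gap_open, gap_extend)
          e <- evalue(aln$score, nchar(archetypes$residues[i]),
                      nchar(archetypes$residues[j]), ka_params)
          aln$identity >= threshold && e <= max_link_evalue
        } else {
          percent_identity(archetypes$residues[i], archetypes$residues[j],
                           matrix, gap_open, gap_extend,
                           mode = "global") >= threshold
        }
        if (linked) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- lapply(split(seq_len(n), root), function(idx) {
    members <- archetypes[idx, , drop = FALSE]
    class(members) <- c("SequenceSet", "data.frame")
    labels <- unique(members$function_label[!is.na(members$function_label)])
    homologous_group(name = paste(labels, collapse = "_"), members = members,
                     archetype_ids = members$id)
  })
  names(groups) <- vapply(groups, function(g) g$name, character(1))
  groups
}
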