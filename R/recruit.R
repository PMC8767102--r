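# Homolog recruitment under conjunctive query-coverage and E-value filters,
# and compaction (dereplication + identity clustering) of the recruit set.
# Archetypes (evidence verified/putative) are never dropped.

#' Recruit homologous database sequences into a group
#'
#' For each archetype, every database sequence passing BOTH the query-coverage
#' and E-value filters (local alignment, coverage measured on the archetype)
#' is added with evidence `recruited`. Archetypes are always retained and
#' each recruited id appears once per group (hits are pooled per group).
#'
#' @param group a [homologous_group()].
#' @param database a `SequenceSet` to recruit from.
#' @param min_qcov minimum query coverage (default 0.70); hits strictly below
#'   are excluded.
#' @param max_evalue maximum E-value (default 1e-4).
#' @param backend either `"builtin"` (local Smith-Waterman plus
#'   Karlin-Altschul E-values) or a function `(group, database)` returning a
#'   data frame with columns `query`, `target`, `score`, `qcov`, `evalue`
#'   (an external-search adapter).
#' @param matrix,gap_open,gap_extend,ka_params built-in backend parameters.
#' @return the expanded `HomologousGroup`.
#' @export
recruit_homologs <- function(group, database, min_qcov = 0.70,
                             max_evalue = 1e-4, backend = "builtin",
                             matrix = blosum62(), gap_open = 11,
                             gap_extend = 1,
                             ka_params = karlin_altschul_params()) {
  stopifnot(inherits(group, "HomologousGroup"))
  validate_sequence_set(database)
  if (nrow(database) == 0) stop("database must be non-empty")
  if (min_qcov < 0 || min_qcov > 1 || max_evalue <= 0)
    stop("invalid recruitment thresholds")

  hits <- if (is.function(backend)) {
    h <- tryCatch(backend(group, database),
                  error = function(e) stop("search backend failed for group '",
                                           group$name, "': ",
                                           conditionMessage(e)))
    stopifnot(all(c("query", "target", "qcov", "evalue") %in% names(h)))
    h
  } else {
    arch <- group$members[group$members$id %in% group$archetype_ids, ]
    n_res <- sum(nchar(database$residues))
    do.call(rbind, lapply(seq_len(nrow(arch)), function(i) {
      scan <- cpp_align_scan(arch$residues[i], database$residues, matrix,
                             gap_open, gap_extend, TRUE, FALSE)
      data.frame(query = arch$id[i], target = database$id,
                 score = scan$score, qcov = scan$qcov,
                 evalue = evalue(scan$score, m = nchar(arch$residues[i]),
                                 n = n_res, params = ka_params),
                 stringsAsFactors = FALSE)
    }))
  }

  keep <- hits$qcov >= min_qcov & hits$evalue <= max_evalue
  new_ids <- setdiff(unique(hits$target[keep]), group$members$id)
  recruits <- database[database$id %in% new_ids, , drop = FALSE]
  if (nrow(recruits) > 0) {
    recruits$evidence <- "recruited"
    members <- rbind(group$members, recruits)
  } else members <- group$members
  class(members) <- c("SequenceSet", "data.frame")
  homologous_group(group$name, members, group$archetype_ids)
}

# archetype-priority representative: verified > putative > recruited/unknown,
# then input order within the group
pick_representative <- function(member_ids, members) {
  sub <- members[match(member_ids, members$id), ]
  pr <- match(sub$evidence, c("verified", "putative", "recruited", "unknown"))
  sub$id[order(pr, match(sub$id, members$id))][1]
}

#' Compact a recruited group by dereplication and identity clustering
#'
#' Removes byte-identical duplicates, then keeps one representative per
#' identity cluster (default 98%). Archetypes are protected: an archetype is
#' always chosen as its cluster's representative (priority verified >
#' putative > recruited, then input order), and every archetype survives even
#' when several fall into one cluster, so that downstream clade extraction
#' always finds its verified leaves.
#'
#' @param group an expanded `HomologousGroup`.
#' @param derep dereplicate exact duplicates first (default TRUE).
#' @param cluster_identity identity threshold for clustering (default 0.98);
#'   `NA` skips the clustering step.
#' @param matrix,gap_open,gap_extend alignment parameters.
#' @return the compacted `HomologousGroup`.
#' @export
compact_recruits <- function(group, derep = TRUE, cluster_identity = 0.98,
                             matrix = blosum62(), gap_open = 11,
                             gap_extend = 1) {
  stopifnot(inherits(group, "HomologousGroup"))
  members <- group$members
  if (derep) {
    reps <- vapply(dereplicate(members),
                   function(cl) pick_representative(cl$member_ids, members),
                   character(1))
    keep <- unique(c(reps, group$archetype_ids))
    members <- members[members$id %in% keep, , drop = FALSE]
    class(members) <- c("SequenceSet", "data.frame")
  }
  if (!is.na(cluster_identity)) {
    clusters <- greedy_cluster(members, cluster_identity, matrix, gap_open,
                               gap_extend)
    reps <- vapply(clusters,
                   function(cl) pick_representative(cl$member_ids, members),
                   character(1))
    keep <- unique(c(reps, group$archetype_ids))
    members <- members[members$id %in% keep, , drop = FALSE]
    class(members) <- c("SequenceSet", "data.frame")
  }
  homologous_group(group$name, members, group$archetype_ids)
}
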