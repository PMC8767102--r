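# Profile-HMM construction from seed alignments and bit-score search.
# Match columns are alignment columns with gap fraction < 0.5; emissions are
# Henikoff-weighted counts with background-proportional pseudocounts;
# transitions come from the observed state paths with +1 pseudocounts.
# Scores are local Viterbi log-odds in bits against the background null
# (best single-domain score; no zero floor).

is_gap <- function(ch) ch == "-" | ch == "."

aln_char_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(unclass(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

#' Henikoff position-based sequence weights
#'
#' Each column distributes one unit of weight over its residues,
#' 1/(types x count-of-own-type) per sequence; weights are normalized to mean
#' one so that total counts equal the number of rows.
#'
#' @param alignment a `ProteinAlignment`.
#' @return named numeric weights, one per row, summing to the row count.
#' @export
henikoff_weights <- function(alignment) {
  m <- aln_char_matrix(alignment)
  w <- numeric(nrow(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    res <- !is_gap(col)
    if (!any(res)) next
    tab <- table(col[res])
    r <- length(tab)
    w[res] <- w[res] + 1 / (r * as.numeric(tab[col[res]]))
  }
  if (all(w == 0)) w <- rep(1, nrow(m))
  w <- w * nrow(m) / sum(w)
  stats::setNames(w, rownames(m))
}

#' Build a profile HMM from a seed alignment
#'
#' @param alignment a `ProteinAlignment` (>= 1 row). A warning is issued for
#'   alignments with fewer than 5 rows, where the model generalizes poorly.
#' @param name model name.
#' @param pseudocount_weight weight of the background-proportional emission
#'   pseudocounts (Laplace-style; default 1).
#' @param background amino-acid background frequencies.
#' @param weights `"henikoff"` (position-based; default) or `"uniform"`.
#' @return a [profile_hmm()].
#' @export
build_hmm <- function(alignment, name, pseudocount_weight = 1.0,
                      background = background_frequencies(),
                      weights = c("henikoff", "uniform")) {
  weights <- match.arg(weights)
  stopifnot(inherits(alignment, "ProteinAlignment"), length(alignment) >= 1,
            pseudocount_weight > 0)
  if (length(alignment) < 5)
    warning("model '", name, "' built from fewer than 5 seed sequences")
  m <- aln_char_matrix(alignment)
  nseq <- nrow(m)
  gapfrac <- colMeans(is_gap(m))
  match_cols <- which(gapfrac < 0.5)
  M <- length(match_cols)
  if (M == 0) stop("alignment has no match columns (gap fraction < 0.5)")
  w <- if (weights == "henikoff") henikoff_weights(alignment) else
    stats::setNames(rep(1, nseq), rownames(m))

  bg <- background / sum(background)
  me <- matrix(0, M, 20, dimnames = list(NULL, AMINO_ALPHABET))
  ie <- matrix(0, M, 20, dimnames = list(NULL, AMINO_ALPHABET))
  # column -> node of its insert state: number of match columns at or before it
  node_of_col <- cumsum(seq_len(ncol(m)) %in% match_cols)

  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    use <- !is_gap(col) & col %in% AMINO_ALPHABET  # X contributes no counts
    if (!any(use)) next
    k <- node_of_col[j]
    if (j %in% match_cols) {
      me[k, ] <- me[k, ] + vapply(AMINO_ALPHABET,
                                  function(a) sum(w[use & col == a]),
                                  numeric(1))
    } else {
      ki <- max(k, 1L)  # inserts ahead of the first match column go to node 1
      ie[ki, ] <- ie[ki, ] + vapply(AMINO_ALPHABET,
                                    function(a) sum(w[use & col == a]),
                                    numeric(1))
    }
  }
  norm_emission <- function(counts) {
    tot <- rowSums(counts)
    (counts + pseudocount_weight * matrix(bg, nrow(counts), 20, byrow = TRUE)) /
      (tot + pseudocount_weight)
  }
  me <- norm_emission(me)
  ie <- norm_emission(ie)

  # transition counts from the observed state paths (weighted), +1 pseudocount
  tc <- matrix(0, M + 1, 7, dimnames = list(NULL, TRANS_NAMES))
  is_match_col <- seq_len(ncol(m)) %in% match_cols
  for (s in seq_len(nseq)) {
    prev_state <- "M"; prev_node <- 0L
    add <- function(nm) tc[prev_node + 1L, nm] <<- tc[prev_node + 1L, nm] + w[s]
    for (j in seq_len(ncol(m))) {
      ch <- m[s, j]
      if (is_match_col[j]) {
        state <- if (is_gap(ch)) "D" else "M"
        add(paste0(prev_state, state))
        prev_state <- state; prev_node <- node_of_col[j]
      } else if (!is_gap(ch)) {
        add(paste0(prev_state, "I"))
        prev_state <- "I"  # insert state of node prev_node
      }
    }
    add(paste0(prev_state, "M"))  # exit to E counts as ->M at the final node
  }
  tc[, c("MM", "MI", "MD", "IM", "II")] <- tc[, c("MM", "MI", "MD", "IM", "II")] + 1
  tc[2:(M + 1), c("DM", "DD")] <- tc[2:(M + 1), c("DM", "DD")] + 1
  tc[M + 1, c("MD", "DD")] <- 0  # final node cannot enter a delete state
  tr <- tc
  tr[, c("MM", "MI", "MD")] <- tc[, c("MM", "MI", "MD")] /
    rowSums(tc[, c("MM", "MI", "MD"), drop = FALSE])
  tr[, c("IM", "II")] <- tc[, c("IM", "II")] /
    rowSums(tc[, c("IM", "II"), drop = FALSE])
  dsum <- rowSums(tc[, c("DM", "DD"), drop = FALSE])
  tr[, c("DM", "DD")] <- ifelse(cbind(dsum, dsum) > 0,
                                tc[, c("DM", "DD")] / cbind(dsum, dsum),
                                cbind(rep(1, M + 1), rep(0, M + 1)))
  tr[1, c("DM", "DD")] <- c(1, 0)  # node 0 has no delete state

  profile_hmm(name, me, ie, tr, background = bg)
}

# log2-odds matrices for the Viterbi core
hmm_log2odds <- function(hmm) {
  bg <- matrix(hmm$background, hmm$M, 20, byrow = TRUE)
  list(mlo = log2(hmm$match_emissions / bg),
       ilo = log2(hmm$insert_emissions / bg),
       tlo = log2(hmm$transitions))
}

#' Score a protein sequence against a profile HMM
#'
#' Local (Smith-Waterman-style) Viterbi over the profile in log-odds bits
#' against the background null: best single-domain score, uniform entry over
#' match states, free exit, no zero floor (negative scores are reported).
#' `X` residues emit at background frequency (zero log-odds).
#'
#' @param hmm a `ProfileHMM`.
#' @param sequence a protein sequence string, or character vector of them.
#' @return numeric bit score(s).
#' @export
score_sequence <- function(hmm, sequence) {
  stopifnot(inherits(hmm, "ProfileHMM"))
  lo <- hmm_log2odds(hmm)
  cpp_viterbi_batch(lo$mlo, lo$ilo, lo$tlo, toupper(sequence))
}

#' Search a set of HMMs against a set of proteins
#'
#' All (hmm, protein) pairs scoring at or above the reporting floor, in
#' deterministic order: HMM name, then descending score, then target id.
#'
#' @param hmms a list of `ProfileHMM` objects (>= 1).
#' @param proteins a `SequenceSet`.
#' @param floor reporting floor in bits (default 0).
#' @return data frame of hits: `hmm_name`, `target_id`, `bit_score`.
#' @export
search_all <- function(hmms, proteins, floor = 0) {
  if (inherits(hmms, "ProfileHMM")) hmms <- list(hmms)
  stopifnot(length(hmms) >= 1)
  validate_sequence_set(proteins)
  if (nrow(proteins) == 0)
    return(data.frame(hmm_name = character(), target_id = character(),
                      bit_score = numeric(), stringsAsFactors = FALSE))
  hits <- do.call(rbind, lapply(hmms, function(h) {
    sc <- score_sequence(h, proteins$residues)
    keep <- sc >= floor
    data.frame(hmm_name = rep(h$name, sum(keep)), target_id = proteins$id[keep],
               bit_score = sc[keep], stringsAsFactors = FALSE)
  }))
  hits[order(hits$hmm_name, -hits$bit_score, hits$target_id,
             method = "radix"), , drop = FALSE]
}

#' Consensus sequence of a profile HMM
#' @param hmm a `ProfileHMM`.
#' @return string of per-node argmax match residues.
#' @export
consensus_sequence <- function(hmm) {
  paste(AMINO_ALPHABET[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}
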