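# Pairwise global/local protein alignment, percent identity and
# Karlin-Altschul E-value statistics. The dynamic programming lives in
# src/align.cpp; defaults are the community standards for protein homology
# (BLOSUM62, gap open 11, extend 1). Traceback ties break deterministically
# (diagonal > up > left) for bit-exact reproducibility.

#' Default protein substitution matrix (BLOSUM62)
#' @return the BLOSUM62 matrix shipped with Biostrings.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global (Needleman-Wunsch) pairwise alignment with affine gaps
#'
#' A gap of length L costs `gap_open + L * gap_extend`. Identity is computed
#' over aligned columns excluding terminal-gap overhang (see
#' `identity_denominator` for the alternative shorter-sequence denominator,
#' matching common clustering-tool semantics).
#'
#' @param a,b protein sequences (non-empty strings).
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param identity_denominator `"columns"` (aligned columns excluding terminal
#'   overhangs; default) or `"shorter_seq"`.
#' @return a `PairwiseAlignment` list: `a_aln`, `b_aln`, `score`, `identity`,
#'   `query_coverage`.
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = 11,
                         gap_extend = 1,
                         identity_denominator = c("columns", "shorter_seq")) {
  identity_denominator <- match.arg(identity_denominator)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- cpp_align(a, b, matrix, gap_open, gap_extend, FALSE,
                 identity_denominator == "shorter_seq")
  structure(list(a_aln = r$a_aln, b_aln = r$b_aln, score = r$score,
                 identity = r$identity, query_coverage = r$qcov,
                 matches = r$matches, columns = r$columns, mode = "global"),
            class = "PairwiseAlignment")
}

#' Local (Smith-Waterman) pairwise alignment with affine gaps
#'
#' Query coverage is the fraction of query residues inside the aligned span.
#' An all-mismatch pair yields score 0 and an empty alignment.
#'
#' @inheritParams global_align
#' @param query,target protein sequences.
#' @return a `PairwiseAlignment` (see [global_align()]).
#' @export
local_align <- function(query, target, matrix = blosum62(), gap_open = 11,
                        gap_extend = 1,
                        identity_denominator = c("columns", "shorter_seq")) {
  identity_denominator <- match.arg(identity_denominator)
  if (!nzchar(query) || !nzchar(target)) stop("sequences must be non-empty")
  r <- cpp_align(query, target, matrix, gap_open, gap_extend, TRUE,
                 identity_denominator == "shorter_seq")
  structure(list(a_aln = r$a_aln, b_aln = r$b_aln, score = r$score,
                 identity = r$identity, query_coverage = r$qcov,
                 matches = r$matches, columns = r$columns, mode = "local"),
            class = "PairwiseAlignment")
}

#' @export
print.PairwiseAlignment <- function(x, ...) {
  cat(sprintf("PairwiseAlignment (%s): score %.1f, identity %.3f, qcov %.3f\n",
              x$mode, x$score, x$identity, x$query_coverage))
  invisible(x)
}

#' Percent identity of two sequences
#'
#' Identical residue pairs divided by alignment columns excluding
#' terminal-gap overhang (global alignment backbone) or by local-alignment
#' columns when `mode = "local"`. Symmetric in its arguments.
#'
#' @inheritParams global_align
#' @param mode `"global"` (default) or `"local"` (blastp-like) alignment span.
#' @return identity fraction in `[0, 1]`.
#' @export
percent_identity <- function(a, b, matrix = blosum62(), gap_open = 11,
                             gap_extend = 1, mode = c("global", "local"),
                             identity_denominator = c("columns", "shorter_seq")) {
  mode <- match.arg(mode)
  aln <- if (mode == "global")
    global_align(a, b, matrix, gap_open, gap_extend, identity_denominator)
  else local_align(a, b, matrix, gap_open, gap_extend, identity_denominator)
  aln$identity
}

#' Karlin-Altschul parameters for local-alignment E-values
#'
#' The statistic the homology-search E-value filter (<= 1e-4) applies to. Lambda
#' and K are configuration constants (defaults: gapped BLOSUM62 values),
#' not fitted: the filters that use them only require monotonicity in score.
#'
#' @param lambda nats per score unit (> 0).
#' @param K dimensionless constant (> 0).
#' @return an object of class `KarlinAltschulParams`.
#' @export
karlin_altschul_params <- function(lambda = 0.267, K = 0.041) {
  stopifnot(lambda > 0, K > 0)
  structure(list(lambda = lambda, K = K), class = "KarlinAltschulParams")
}

#' E-value of a local alignment raw score
#'
#' `E = K * m * n * exp(-lambda * score)`; strictly decreasing in score and
#' linear in both sequence-space sizes.
#'
#' @param raw_score alignment raw score (substitution-matrix units).
#' @param m query length (> 0).
#' @param n database size in residues (> 0).
#' @param params a [karlin_altschul_params()].
#' @return the expected number of chance hits at this score.
#' @export
evalue <- function(raw_score, m, n, params = karlin_altschul_params()) {
  if (any(m <= 0) || any(n <= 0)) stop("m and n must be positive")
  params$K * m * n * exp(-params$lambda * raw_score)
}
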