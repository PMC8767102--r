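# Reference implementations used to check the optimized C++ kernels.
# These are deliberately naive exhaustive enumerations (no dynamic
# programming): every alignment path / every Viterbi state path is visited,
# so agreement with the package is evidence of correctness, not of shared
# bugs. Only usable on tiny instances.

# exhaustive global affine-gap alignment score: recursion over all monotone
# paths; a gap of length L costs open + L * ext
oracle_global_score <- function(a, b, sub = blosum62(), open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  rec <- function(i, j, prev) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    if (i <= n)
      best <- max(best,
                  -(if (prev == "X") ext else open + ext) + rec(i + 1, j, "X"))
    if (j <= m)
      best <- max(best,
                  -(if (prev == "Y") ext else open + ext) + rec(i, j + 1, "Y"))
    best
  }
  rec(1, 1, "M")
}

# exhaustive local score: best global score over all substring pairs, floored
# at zero (every local alignment is a full alignment of two substrings)
oracle_local_score <- function(a, b, sub = blosum62(), open = 11, ext = 1) {
  n <- nchar(a)
  m <- nchar(b)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      sb <- substr(b, j1, j2)
      best <- max(best, oracle_global_score(sa, sb, sub, open, ext))
    }
  }
  best
}

# exhaustive local profile Viterbi in log2-odds bits: enumerate every state
# path (entry = log2(1/M) into any match state at any sequence position;
# exit free from any match state; insert states 1..M-1; X residues emit at
# background, i.e. zero log-odds)
oracle_viterbi_score <- function(hmm, seq) {
  lo <- hmmforge:::hmm_log2odds(hmm)
  M <- hmm$M
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  em <- function(k, i) {
    a <- match(chars[i], alpha)
    if (is.na(a)) 0 else lo$mlo[k, a]
  }
  ei <- function(k, i) {
    a <- match(chars[i], alpha)
    if (is.na(a)) 0 else lo$ilo[k, a]
  }
  # transitions out of node k live in row k + 1 (row 1 = node 0)
  tr <- function(k, name) lo$tlo[k + 1, name]
  # best continuation after emitting position i in state (match k / insert k /
  # delete k); exit is free from match states only
  rec_m <- function(i, k) {
    best <- 0  # exit
    if (i < L && k < M)
      best <- max(best, tr(k, "MM") + em(k + 1, i + 1) + rec_m(i + 1, k + 1))
    if (i < L && k < M)
      best <- max(best, tr(k, "MI") + ei(k, i + 1) + rec_i(i + 1, k))
    if (k < M)
      best <- max(best, tr(k, "MD") + rec_d(i, k + 1))
    best
  }
  rec_i <- function(i, k) {
    best <- -Inf
    if (i < L)
      best <- max(best, tr(k, "IM") + em(k + 1, i + 1) + rec_m(i + 1, k + 1))
    if (i < L)
      best <- max(best, tr(k, "II") + ei(k, i + 1) + rec_i(i + 1, k))
    best
  }
  rec_d <- function(i, k) {
    best <- -Inf
    if (i < L && k < M)
      best <- max(best, tr(k, "DM") + em(k + 1, i + 1) + rec_m(i + 1, k + 1))
    if (k < M)
      best <- max(best, tr(k, "DD") + rec_d(i, k + 1))
    best
  }
  best <- -Inf
  for (i in seq_len(L)) for (k in seq_len(M))
    best <- max(best, -log2(M) + em(k, i) + rec_m(i, k))
  best
}

# identity recount from aligned strings: matches / columns inside the aligned
# core (terminal overhang excluded)
oracle_identity <- function(a_aln, b_aln) {
  av <- strsplit(a_aln, "")[[1]]
  bv <- strsplit(b_aln, "")[[1]]
  core <- which(av != "-" & bv != "-")
  if (length(core) == 0) return(0)
  idx <- seq(min(core), max(core))
  sum(av[idx] == bv[idx] & av[idx] != "-" & bv[idx] != "-") / length(idx)
}
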