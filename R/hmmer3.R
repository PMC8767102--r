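# Profile HMM container and HMMER3 ASCII ("HMMER3/f") input/output.
#
# Probabilities are stored in probability space; files store negative natural
# logs with '*' for zero. Transitions are kept in HMMER node layout: row k
# (0-based node index; row 1 of the R matrix is node 0) holds the seven
# probabilities out of node k: M->M, M->I, M->D, I->M, I->I, D->M, D->D.

TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

# Robinson & Robinson (1991) amino-acid background frequencies, the standard
# null composition used by profile-HMM software.
ROBINSON_BACKGROUND <- c(
  A = 0.0787945, C = 0.0151600, D = 0.0535222, E = 0.0668298,
  F = 0.0397062, G = 0.0695071, H = 0.0229198, I = 0.0590092,
  K = 0.0594422, L = 0.0963728, M = 0.0237718, N = 0.0414386,
  P = 0.0482904, Q = 0.0395639, R = 0.0540978, S = 0.0683364,
  T = 0.0540687, V = 0.0673417, W = 0.0114135, Y = 0.0304133
)
ROBINSON_BACKGROUND <- ROBINSON_BACKGROUND / sum(ROBINSON_BACKGROUND)

#' Amino-acid background frequencies
#'
#' @param kind `"robinson"` (Robinson & Robinson composition; default) or
#'   `"uniform"`.
#' @return named numeric vector of 20 frequencies summing to 1.
#' @export
background_frequencies <- function(kind = c("robinson", "uniform")) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    bg <- rep(1 / 20, 20)
    names(bg) <- AMINO_ALPHABET
    bg
  } else ROBINSON_BACKGROUND
}

#' Trusted/noise bit-score cutoff pair
#'
#' The trusted cutoff is the bit score at/above which a hit is confidently
#' annotated with the HMM's function; the noise cutoff is the score below
#' which hits are deemed functionally unrelated. `noise <= trusted` always.
#'
#' @param trusted trusted bit score.
#' @param noise noise bit score.
#' @param flags optional character vector of diagnostic flags (e.g.
#'   `"overlap_conflict"`).
#' @return an object of class `CutoffPair`.
#' @export
cutoff_pair <- function(trusted, noise, flags = character()) {
  stopifnot(is.finite(trusted), is.finite(noise))
  if (noise > trusted) stop("noise cutoff must not exceed trusted cutoff")
  structure(list(trusted = as.numeric(trusted), noise = as.numeric(noise),
                 flags = as.character(flags)),
            class = "CutoffPair")
}

#' Construct a profile HMM
#'
#' @param name model name.
#' @param match_emissions M x 20 matrix of match-state emission probabilities
#'   (columns in alphabet order `ACDEFGHIKLMNPQRSTVWY`).
#' @param insert_emissions M x 20 matrix of insert-state emission
#'   probabilities.
#' @param transitions (M+1) x 7 matrix of per-node transition probabilities
#'   (columns `MM, MI, MD, IM, II, DM, DD`; row 1 is node 0).
#' @param background length-20 background frequencies.
#' @param cutoffs optional [cutoff_pair()].
#' @return an object of class `ProfileHMM`.
#' @export
profile_hmm <- function(name, match_emissions, insert_emissions, transitions,
                        background = background_frequencies(), cutoffs = NULL) {
  M <- nrow(match_emissions)
  stopifnot(M >= 1, ncol(match_emissions) == 20,
            identical(dim(insert_emissions), dim(match_emissions)),
            nrow(transitions) == M + 1, ncol(transitions) == 7,
            length(background) == 20)
  colnames(match_emissions) <- colnames(insert_emissions) <- AMINO_ALPHABET
  colnames(transitions) <- TRANS_NAMES
  names(background) <- AMINO_ALPHABET
  x <- structure(list(name = as.character(name), M = M,
                      match_emissions = match_emissions,
                      insert_emissions = insert_emissions,
                      transitions = transitions,
                      background = background / sum(background),
                      cutoffs = cutoffs),
                 class = "ProfileHMM")
  validate_profile_hmm(x)
  x
}

#' Validate a ProfileHMM
#'
#' Checks that every emission row and transition bundle sums to 1 within
#' 1e-9, that emission probabilities are strictly positive, and that the
#' cutoff pair (if any) is valid.
#'
#' @param x a `ProfileHMM`.
#' @param tol normalization tolerance.
#' @return `x`, invisibly, or an error.
#' @export
validate_profile_hmm <- function(x, tol = 1e-9) {
  for (what in c("match_emissions", "insert_emissions")) {
    e <- x[[what]]
    if (any(e <= 0)) stop(what, " must be strictly positive after pseudocounts")
    if (any(abs(rowSums(e) - 1) > tol)) stop(what, " rows must sum to 1")
  }
  tr <- x$transitions
  if (any(tr < 0)) stop("negative transition probability")
  bundles <- cbind(rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE]),
                   rowSums(tr[, c("IM", "II"), drop = FALSE]),
                   rowSums(tr[, c("DM", "DD"), drop = FALSE]))
  if (any(abs(bundles - 1) > tol)) stop("transition bundles must sum to 1")
  if (tr[x$M + 1, "MD"] != 0 || tr[x$M + 1, "DD"] != 0)
    stop("final node cannot transition to a delete state")
  if (!is.null(x$cutoffs) && !inherits(x$cutoffs, "CutoffPair"))
    stop("cutoffs must be a CutoffPair or NULL")
  invisible(x)
}

#' @export
print.ProfileHMM <- function(x, ...) {
  cat(sprintf("ProfileHMM '%s': M = %d%s\n", x$name, x$M,
              if (!is.null(x$cutoffs))
                sprintf(", trusted = %.1f, noise = %.1f",
                        x$cutoffs$trusted, x$cutoffs$noise) else ""))
  invisible(x)
}

prob_to_nll <- function(p) ifelse(p <= 0, Inf, -log(p))
nll_to_prob <- function(x) ifelse(is.infinite(x), 0, exp(-x))

fmt_nll <- function(x) ifelse(is.infinite(x), "      *", sprintf("%8.5f", x))

#' Read profile HMMs from a HMMER3 ASCII file
#'
#' Parses the "HMMER3/f" dialect (the format written by `hmmbuild`),
#' including optional `TC`/`NC` cutoff lines which become a [cutoff_pair()].
#' Multiple concatenated models are supported. Only the amino alphabet is
#' accepted. Log-probability tables are converted to probabilities.
#'
#' @param path path to a `.hmm` file.
#' @param background background frequencies to attach to the parsed models
#'   (the file format does not store a null composition).
#' @return a list of [profile_hmm()] objects, named by model name.
#' @export
read_hmmer3 <- function(path, background = background_frequencies()) {
  lines <- readLines(path)
  models <- list()
  i <- 1
  n <- length(lines)
  num <- function(tok) ifelse(tok == "*", Inf, suppressWarnings(as.numeric(tok)))
  while (i <= n) {
    while (i <= n && !grepl("^HMMER3", lines[i])) i <- i + 1
    if (i > n) break
    if (!grepl("^HMMER3/f", lines[i]))
      stop("unsupported HMMER save-file dialect at line ", i, ": ", lines[i])
    hdr <- list()
    i <- i + 1
    while (i <= n && !grepl("^HMM\\s", lines[i])) {
      key <- sub("^(\\S+).*$", "\\1", lines[i])
      val <- trimws(sub("^\\S+\\s*", "", lines[i]))
      hdr[[key]] <- val
      i <- i + 1
    }
    if (i > n) stop("truncated model: no HMM line before end of file")
    if (is.null(hdr$ALPH) || tolower(hdr$ALPH) != "amino")
      stop("unsupported alphabet '", hdr$ALPH, "' (only amino is supported)")
    M <- as.integer(hdr$LENG)
    name <- if (!is.null(hdr$NAME)) hdr$NAME else "unnamed"
    cutoffs <- NULL
    if (!is.null(hdr$TC) && !is.null(hdr$NC)) {
      tc <- num(strsplit(gsub(";", "", hdr$TC), "\\s+")[[1]][1])
      nc <- num(strsplit(gsub(";", "", hdr$NC), "\\s+")[[1]][1])
      cutoffs <- cutoff_pair(trusted = tc, noise = nc)
    }
    i <- i + 2  # skip the HMM alphabet line and the transition header line
    toks <- function(line) strsplit(trimws(line), "\\s+")[[1]]
    if (grepl("^\\s*COMPO", lines[i])) i <- i + 1
    i <- i + 2  # node-0 insert emission and transition lines
    me <- matrix(0, M, 20)
    ie <- matrix(0, M, 20)
    tr <- matrix(0, M + 1, 7)
    # node 0 transitions (the line just skipped)
    tr[1, ] <- nll_to_prob(num(toks(lines[i - 1])[1:7]))
    for (k in seq_len(M)) {
      if (i + 2 > n) stop("truncated model '", name, "' near line ", i)
      mt <- toks(lines[i])
      if (as.integer(mt[1]) != k)
        stop("parse error at line ", i, ": expected node ", k)
      me[k, ] <- nll_to_prob(num(mt[2:21]))
      ie[k, ] <- nll_to_prob(num(toks(lines[i + 1])[1:20]))
      tr[k + 1, ] <- nll_to_prob(num(toks(lines[i + 2])[1:7]))
      i <- i + 3
    }
    if (i > n || !grepl("^//", lines[i]))
      stop("truncated model '", name, "': missing // terminator at line ", i)
    i <- i + 1
    # the file stores log-probabilities at finite precision, so rows sum to 1
    # only approximately; renormalize to restore the exact invariant
    me <- me / rowSums(me)
    ie <- ie / rowSums(ie)
    for (bundle in list(1:3, 4:5, 6:7)) {
      s <- rowSums(tr[, bundle, drop = FALSE])
      nz <- s > 0
      tr[nz, bundle] <- tr[nz, bundle, drop = FALSE] / s[nz]
    }
    models[[name]] <- profile_hmm(name, me, ie, tr, background = background,
                                  cutoffs = cutoffs)
  }
  models
}

#' Write profile HMMs to a HMMER3 ASCII file
#'
#' Emits the "HMMER3/f" header verbatim for downstream compatibility, with
#' `TC`/`NC` cutoff lines whenever a model carries cutoffs so consumers can
#' apply them.
#'
#' @param hmms a `ProfileHMM` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmmer3 <- function(hmms, path) {
  if (inherits(hmms, "ProfileHMM")) hmms <- list(hmms)
  con <- file(path, "w")
  on.exit(close(con))
  for (h in hmms) {
    validate_profile_hmm(h)
    out <- c(
      "HMMER3/f [3.4 | hmmforge]",
      sprintf("NAME  %s", h$name),
      sprintf("LENG  %d", h$M),
      "ALPH  amino", "RF    no", "MM    no", "CONS  yes", "CS    no",
      "MAP   yes")
    if (!is.null(h$cutoffs)) {
      out <- c(out,
               sprintf("TC    %.2f %.2f;", h$cutoffs$trusted, h$cutoffs$trusted),
               sprintf("NC    %.2f %.2f;", h$cutoffs$noise, h$cutoffs$noise))
    }
    out <- c(out,
             paste0("HMM     ", paste(sprintf("     %s   ", AMINO_ALPHABET),
                                      collapse = "")),
             paste("        ",
                   paste(sprintf("%8s", TRANS_NAMES_PRETTY), collapse = " ")))
    compo <- colMeans(h$match_emissions)
    out <- c(out, paste0("  COMPO ",
                         paste(fmt_nll(prob_to_nll(compo)), collapse = " ")))
    out <- c(out, paste0("        ",
                         paste(fmt_nll(prob_to_nll(h$insert_emissions[1, ])),
                               collapse = " ")))
    out <- c(out, paste0("        ",
                         paste(fmt_nll(prob_to_nll(h$transitions[1, ])),
                               collapse = " ")))
    for (k in seq_len(h$M)) {
      cons <- AMINO_ALPHABET[which.max(h$match_emissions[k, ])]
      out <- c(out,
               paste0(sprintf("%7d ", k),
                      paste(fmt_nll(prob_to_nll(h$match_emissions[k, ])),
                            collapse = " "),
                      sprintf(" %6d %s - - -", k, cons)),
               paste0("        ",
                      paste(fmt_nll(prob_to_nll(h$insert_emissions[k, ])),
                            collapse = " ")),
               paste0("        ",
                      paste(fmt_nll(prob_to_nll(h$transitions[k + 1, ])),
                            collapse = " ")))
    }
    out <- c(out, "//")
    writeLines(out, con)
  }
  invisible(path)
}

TRANS_NAMES_PRETTY <- c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")
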