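# Trusted/noise cutoff calibration from bit-score distributions: verified
# archetypes versus phylogenetically related off-target sequences (everything
# in the full homologous group that did not make it into the seed set).

#' Score partitions of a homologous group against its HMM
#'
#' Scores every member of the full (pre-pruning) group and partitions the
#' scores into verified archetypes, other in-clade (seed) members, and
#' off-target sequences (everything outside the seed set).
#'
#' @param hmm the group's `ProfileHMM`.
#' @param group the full `HomologousGroup` before pruning.
#' @param seed_ids ids of the seed sequences (from [nested_prune()]).
#' @return list of numeric vectors `verified`, `inclade`, `offtarget`, each
#'   named by sequence id.
#' @export
score_distributions <- function(hmm, group, seed_ids) {
  stopifnot(inherits(hmm, "ProfileHMM"), inherits(group, "HomologousGroup"))
  ver <- verified_ids(group)
  if (length(ver) == 0) stop("group '", group$name, "' has no verified archetype")
  m <- group$members
  sc <- stats::setNames(score_sequence(hmm, m$residues), m$id)
  in_seed <- m$id %in% seed_ids
  is_ver <- m$id %in% ver
  list(verified = sc[is_ver],
       inclade = sc[in_seed & !is_ver],
       offtarget = sc[!in_seed & !is_ver])
}

#' Choose trusted and noise cutoffs from score distributions
#'
#' The trusted cutoff is the minimum verified score (every experimentally
#' verified gene scores at or above it); the noise cutoff sits just above the
#' highest off-target score (`max + epsilon`), or collapses onto the trusted
#' cutoff when there are no off-targets. When the distributions overlap
#' (noise would exceed trusted) the pair collapses to
#' `(trusted, trusted)` and is flagged `overlap_conflict` for manual review.
#' Duplicated score observations do not move the cutoffs.
#'
#' @param verified_scores non-empty numeric vector.
#' @param offtarget_scores numeric vector (possibly empty).
#' @param epsilon margin above the highest off-target score, in bits
#'   (default 0.1).
#' @return a [cutoff_pair()], possibly flagged `overlap_conflict`.
#' @export
choose_cutoffs <- function(verified_scores, offtarget_scores = numeric(),
                           epsilon = 0.1) {
  if (length(verified_scores) == 0) stop("verified scores must be non-empty")
  trusted <- min(verified_scores)
  if (length(offtarget_scores) == 0)
    return(cutoff_pair(trusted, trusted))
  noise <- max(offtarget_scores) + epsilon
  if (noise > trusted)
    return(cutoff_pair(trusted, trusted, flags = "overlap_conflict"))
  cutoff_pair(trusted, noise)
}

#' Attach a cutoff pair to a profile HMM
#'
#' @param hmm a `ProfileHMM`.
#' @param pair a valid [cutoff_pair()] (`noise <= trusted`).
#' @return the `ProfileHMM` with cutoffs embedded; [write_hmmer3()] will emit
#'   the corresponding TC/NC lines.
#' @export
attach_cutoffs <- function(hmm, pair) {
  stopifnot(inherits(hmm, "ProfileHMM"))
  if (!inherits(pair, "CutoffPair")) stop("pair must be a CutoffPair")
  if (pair$noise > pair$trusted) stop("noise cutoff must not exceed trusted")
  hmm$cutoffs <- pair
  hmm
}

#' Per-HMM calibration diagnostics table
#'
#' @param dists output of [score_distributions()].
#' @return data frame with id, bit_score and partition columns, ordered by
#'   descending score.
#' @export
calibration_table <- function(dists) {
  block <- function(v, part) {
    data.frame(id = if (length(v)) names(v) else character(),
               bit_score = unname(v),
               partition = rep(part, length(v)), stringsAsFactors = FALSE)
  }
  out <- rbind(block(dists$verified, "verified"),
               block(dists$inclade, "inclade"),
               block(dists$offtarget, "offtarget"))
  out <- out[order(-out$bit_score, out$id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score-histogram plot for one HMM's calibration
#'
#' @param dists output of [score_distributions()].
#' @param pair the chosen [cutoff_pair()].
#' @param path output PNG path.
#' @param title plot title.
#' @return `path`, invisibly.
#' @export
plot_score_distributions <- function(dists, pair, path, title = "") {
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  all_sc <- c(dists$verified, dists$inclade, dists$offtarget)
  brk <- pretty(range(all_sc, pair$trusted, pair$noise), n = 40)
  graphics::plot(NA, xlim = range(brk), ylim = c(0, 1), main = title,
                 xlab = "bit score", ylab = "frequency", yaxs = "i")
  cols <- c(offtarget = "grey70", inclade = "steelblue", verified = "darkgreen")
  ymax <- 1
  for (part in names(cols)) {
    v <- dists[[part]]
    if (length(v) == 0) next
    h <- graphics::hist(v, breaks = brk, plot = FALSE)
    ymax <- max(ymax, h$counts)
  }
  graphics::plot(NA, xlim = range(brk), ylim = c(0, ymax), main = title,
                 xlab = "bit score", ylab = "count", yaxs = "i")
  for (part in names(cols)) {
    v <- dists[[part]]
    if (length(v) == 0) next
    graphics::hist(v, breaks = brk, col = cols[[part]], add = TRUE, border = NA)
  }
  graphics::abline(v = pair$trusted, col = "darkgreen", lwd = 2)
  graphics::abline(v = pair$noise, col = "red", lwd = 2, lty = 2)
  invisible(path)
}
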