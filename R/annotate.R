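# Genome/metagenome annotation with a cutoff-bearing HMM database:
# confidence tiers, best-HMM resolution per gene, per-million normalization
# and substrate/respiration summary tables.

TIERS <- c("confident", "ambiguous", "rejected")

#' Classify a bit score against a cutoff pair
#'
#' Inclusive boundaries at both cutoffs: `score >= trusted` is confident,
#' `noise <= score < trusted` is ambiguous, `score < noise` is rejected.
#'
#' @param score bit score(s).
#' @param cutoffs a [cutoff_pair()].
#' @return character tier(s).
#' @export
classify_hit <- function(score, cutoffs) {
  stopifnot(inherits(cutoffs, "CutoffPair"))
  ifelse(score >= cutoffs$trusted, "confident",
         ifelse(score >= cutoffs$noise, "ambiguous", "rejected"))
}

#' Resolve one gene's hits to a single annotation record
#'
#' Among confident hits the highest-scoring HMM wins (ties break to the
#' lexicographically smallest HMM name); with no confident hit the best
#' ambiguous hit is recorded as ambiguous; otherwise the gene is rejected and
#' carries no assignment.
#'
#' @param hits data frame of hits for ONE gene: `hmm_name`, `target_id`,
#'   `bit_score`.
#' @param database named list of cutoff-bearing `ProfileHMM` objects.
#' @return one-row data frame: `gene_id`, `assigned_hmm`, `bit_score`, `tier`.
#' @export
assign_best <- function(hits, database) {
  if (nrow(hits) == 0) stop("empty hit set")
  if (length(unique(hits$target_id)) != 1)
    stop("assign_best expects hits for a single gene")
  gene <- hits$target_id[1]
  tier <- vapply(seq_len(nrow(hits)), function(i) {
    h <- database[[hits$hmm_name[i]]]
    if (is.null(h) || is.null(h$cutoffs))
      stop("no cutoffs for HMM '", hits$hmm_name[i], "'")
    classify_hit(hits$bit_score[i], h$cutoffs)
  }, character(1))
  pick <- function(idx) {
    idx <- idx[order(-hits$bit_score[idx], hits$hmm_name[idx],
                     method = "radix")]
    idx[1]
  }
  conf <- which(tier == "confident")
  amb <- which(tier == "ambiguous")
  if (length(conf) > 0) {
    i <- pick(conf)
    data.frame(gene_id = gene, assigned_hmm = hits$hmm_name[i],
               bit_score = hits$bit_score[i], tier = "confident",
               stringsAsFactors = FALSE)
  } else if (length(amb) > 0) {
    i <- pick(amb)
    data.frame(gene_id = gene, assigned_hmm = hits$hmm_name[i],
               bit_score = hits$bit_score[i], tier = "ambiguous",
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = gene, assigned_hmm = NA_character_,
               bit_score = max(hits$bit_score), tier = "rejected",
               stringsAsFactors = FALSE)
  }
}

# built-in E-value estimate for an HMM hit: database-size-scaled P-value
# under calibrated bit scores
hit_evalue <- function(bit_score, n_targets) n_targets * 2^(-bit_score)

#' Annotate one sample of proteins with an HMM database
#'
#' In `cutoff` mode every input gene appears exactly once: hits are tiered
#' against each model's trusted/noise cutoffs and resolved per gene with
#' [assign_best()]; genes hitting nothing are rejected. In `evalue` mode
#' (emulating generic HMM databases without curated cutoffs) hits are kept by
#' a plain E-value filter with no tiers, using the built-in estimate
#' `E = n_targets * 2^(-bitscore)`.
#'
#' @param proteins a `SequenceSet` of predicted protein sequences.
#' @param database named list of `ProfileHMM` objects (cutoffs required in
#'   `cutoff` mode).
#' @param mode `"cutoff"` (default) or `"evalue"`.
#' @param max_evalue E-value threshold for `evalue` mode (default 1e-50).
#' @return data frame of `AnnotationRecord`s: `gene_id`, `assigned_hmm`,
#'   `bit_score`, `tier` (cutoff mode), or `gene_id`, `assigned_hmm`,
#'   `bit_score`, `evalue` (evalue mode, one row per passing hit).
#' @export
annotate_sample <- function(proteins, database, mode = c("cutoff", "evalue"),
                            max_evalue = 1e-50) {
  mode <- match.arg(mode)
  if (inherits(database, "ProfileHMM")) database <- list(database)
  names(database) <- vapply(database, function(h) h$name, character(1))
  validate_sequence_set(proteins)
  if (mode == "cutoff") {
    missing_cut <- names(database)[vapply(database,
                                          function(h) is.null(h$cutoffs),
                                          logical(1))]
    if (length(missing_cut) > 0)
      stop("cutoff mode requires cutoffs on every model; missing for: ",
           paste(missing_cut, collapse = ", "))
  }
  hits <- search_all(database, proteins, floor = -Inf)
  if (mode == "evalue") {
    hits$evalue <- hit_evalue(hits$bit_score, nrow(proteins))
    out <- hits[hits$evalue <= max_evalue, , drop = FALSE]
    names(out)[names(out) == "hmm_name"] <- "assigned_hmm"
    rownames(out) <- NULL
    return(out[, c("target_id", "assigned_hmm", "bit_score", "evalue")] |>
             stats::setNames(c("gene_id", "assigned_hmm", "bit_score",
                               "evalue")))
  }
  by_gene <- split(hits, hits$target_id)
  recs <- do.call(rbind, lapply(proteins$id, function(g) {
    h <- by_gene[[g]]
    if (is.null(h) || nrow(h) == 0)
      data.frame(gene_id = g, assigned_hmm = NA_character_,
                 bit_score = NA_real_, tier = "rejected",
                 stringsAsFactors = FALSE)
    else assign_best(h, database)
  }))
  rownames(recs) <- NULL
  recs
}

#' Normalize marker counts per million predicted genes
#'
#' @param counts hit counts (numeric vector or matrix).
#' @param total_predicted_genes total predicted protein-coding genes in the
#'   sample (> 0).
#' @return counts scaled to per-million-genes rates.
#' @export
normalize_counts <- function(counts, total_predicted_genes) {
  if (any(total_predicted_genes <= 0))
    stop("total_predicted_genes must be positive")
  counts * 1e6 / total_predicted_genes
}

#' Sample-by-HMM summary table grouped by substrate and respiration
#'
#' @param records_by_sample named list of cutoff-mode [annotate_sample()]
#'   outputs, one per sample.
#' @param metadata a [function_metadata()] covering every HMM in the
#'   database.
#' @param hmm_names the database's HMM names (defaults to the metadata rows).
#' @param total_genes optional named vector of total predicted gene counts per
#'   sample; when given, `rate_per_million` uses it, otherwise the number of
#'   annotated records per sample.
#' @param rate_tier counts entering the rate: `"confident"` (default) or
#'   `"confident_plus_ambiguous"` (hits at or above the noise cutoff).
#' @return long-format data frame: sample, hmm, substrate, respiration,
#'   confident_count, ambiguous_count, rate_per_million; deterministic row
#'   order (sample, then HMM name).
#' @export
summary_matrix <- function(records_by_sample, metadata,
                           hmm_names = metadata$hmm_name, total_genes = NULL,
                           rate_tier = c("confident",
                                         "confident_plus_ambiguous")) {
  rate_tier <- match.arg(rate_tier)
  stopifnot(is.list(records_by_sample), !is.null(names(records_by_sample)))
  miss <- setdiff(hmm_names, metadata$hmm_name)
  if (length(miss) > 0)
    stop("HMM(s) missing from metadata: ", paste(miss, collapse = ", "))
  samples <- names(records_by_sample)
  rows <- do.call(rbind, lapply(samples, function(s) {
    recs <- records_by_sample[[s]]
    tot <- if (!is.null(total_genes)) total_genes[[s]] else nrow(recs)
    do.call(rbind, lapply(sort(hmm_names), function(h) {
      md <- metadata[metadata$hmm_name == h, ]
      conf <- sum(recs$tier == "confident" & recs$assigned_hmm == h,
                  na.rm = TRUE)
      amb <- sum(recs$tier == "ambiguous" & recs$assigned_hmm == h,
                 na.rm = TRUE)
      cnt <- if (rate_tier == "confident") conf else conf + amb
      data.frame(sample = s, hmm = h, substrate = md$substrate,
                 respiration = md$respiration, confident_count = conf,
                 ambiguous_count = amb,
                 rate_per_million = normalize_counts(cnt, tot),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

#' Write a data frame as a TSV report
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
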