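#' @useDynLib hmmforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AMINO_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
EVIDENCE_LEVELS <- c("verified", "putative", "recruited", "unknown")

#' Create a set of protein sequence records
#'
#' A `SequenceSet` is the unit of all curation in hmmforge: a data frame with
#' one row per protein, carrying an evidence level (`verified`, `putative`,
#' `recruited` or `unknown`) and an optional function label (e.g. `"AlkB"`).
#' Verified and putative records are "archetypes": curated references with
#' literature evidence for a specific function.
#'
#' @param id character vector of unique, non-empty sequence identifiers.
#' @param residues character vector of amino-acid strings over the 20-letter
#'   alphabet plus `X`. `*` stop characters are stripped.
#' @param description free-text descriptions.
#' @param evidence one of `"verified"`, `"putative"`, `"recruited"`,
#'   `"unknown"` per record.
#' @param function_label optional function label per record; required when
#'   evidence is `verified` or `putative`.
#' @return an object of class `SequenceSet` (a data frame).
#' @export
sequence_set <- function(id = character(), residues = character(),
                         description = "", evidence = "unknown",
                         function_label = NA_character_) {
  n <- length(id)
  x <- data.frame(
    id = as.character(id),
    description = rep_len(as.character(description), n),
    residues = toupper(gsub("*", "", as.character(residues), fixed = TRUE)),
    evidence = rep_len(as.character(evidence), n),
    function_label = rep_len(as.character(function_label), n),
    stringsAsFactors = FALSE
  )
  class(x) <- c("SequenceSet", "data.frame")
  validate_sequence_set(x)
  x
}

#' Validate a SequenceSet
#'
#' Checks id uniqueness, non-empty residues, alphabet membership and the
#' evidence/function-label contract.
#'
#' @param x a `SequenceSet`.
#' @return `x`, invisibly, or an error.
#' @export
validate_sequence_set <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0) return(invisible(x))
  if (any(!nzchar(x$id)) || anyNA(x$id)) stop("sequence ids must be non-empty")
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0)
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(x$residues)))
    stop("empty sequence for id(s): ",
         paste(x$id[!nzchar(x$residues)], collapse = ", "))
  bad <- vapply(x$residues, function(s) {
    ch <- unique(strsplit(s, "")[[1]])
    paste(setdiff(ch, c(AMINO_ALPHABET, "X")), collapse = "")
  }, character(1))
  if (any(nzchar(bad)))
    stop("non-amino-acid character(s) ",
         paste(unique(unlist(strsplit(bad[nzchar(bad)], ""))), collapse = ""),
         " in sequence(s): ", paste(x$id[nzchar(bad)], collapse = ", "))
  if (!all(x$evidence %in% EVIDENCE_LEVELS))
    stop("evidence must be one of: ", paste(EVIDENCE_LEVELS, collapse = ", "))
  need <- x$evidence %in% c("verified", "putative")
  if (any(need & (is.na(x$function_label) | !nzchar(x$function_label))))
    stop("verified/putative records must carry a function label: ",
         paste(x$id[need & (is.na(x$function_label) | !nzchar(x$function_label))],
               collapse = ", "))
  invisible(x)
}

# parse the `[evidence=...;function=...]` description dialect
parse_label_dialect <- function(desc) {
  evidence <- rep("unknown", length(desc))
  fn <- rep(NA_character_, length(desc))
  m <- regmatches(desc, regexpr("\\[evidence=[^]]*\\]", desc))
  has <- grepl("\\[evidence=[^]]*\\]", desc)
  if (any(has)) {
    inner <- sub("^\\[", "", sub("\\]$", "", m))
    for (i in seq_along(which(has))) {
      idx <- which(has)[i]
      kv <- strsplit(strsplit(inner[i], ";")[[1]], "=")
      for (p in kv) {
        if (length(p) == 2 && p[1] == "evidence") evidence[idx] <- p[2]
        if (length(p) == 2 && p[1] == "function") fn[idx] <- p[2]
      }
    }
  }
  clean <- trimws(gsub("\\s*\\[evidence=[^]]*\\]", "", desc))
  list(evidence = evidence, function_label = fn, description = clean)
}

format_label_dialect <- function(x) {
  tag <- ifelse(
    x$evidence != "unknown" | (!is.na(x$function_label) & nzchar(x$function_label)),
    paste0("[evidence=", x$evidence,
           ifelse(!is.na(x$function_label) & nzchar(x$function_label),
                  paste0(";function=", x$function_label), ""),
           "]"),
    "")
  trimws(paste(x$description, tag))
}

#' Read protein sequences from a FASTA file
#'
#' Sequence lines are concatenated, `*` stop characters stripped and residues
#' upper-cased. Evidence and function labels are recovered from an optional
#' `[evidence=...;function=...]` suffix in the description; records without
#' one default to evidence `"unknown"`.
#'
#' @param path path to a text FASTA file.
#' @return a [sequence_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(sequence_set())
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0) return(sequence_set())
  headers <- names(aa)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  lab <- parse_label_dialect(desc)
  sequence_set(id = id, residues = as.character(aa),
               description = lab$description, evidence = lab$evidence,
               function_label = lab$function_label)
}

#' Write protein sequences to a FASTA file
#'
#' Output is deterministic; evidence/function labels are embedded in the
#' description via the `[evidence=...;function=...]` dialect so that
#' [read_fasta()] round-trips them.
#'
#' @param records a `SequenceSet`.
#' @param path output path.
#' @param wrap sequence line width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  validate_sequence_set(records)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records) > 0) {
    desc <- format_label_dialect(records)
    for (i in seq_len(nrow(records))) {
      hdr <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
      writeLines(paste0(">", hdr), con)
      s <- records$residues[i]
      starts <- seq(1, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1, nchar(s))), con)
    }
  }
  invisible(path)
}

#' Create a homologous group
#'
#' A homologous group is a named collection of sequences (archetypes plus
#' recruited homologs sharing a function neighborhood); it is the unit of
#' profile-HMM construction.
#'
#' @param name group name (becomes the HMM name downstream).
#' @param members a `SequenceSet`.
#' @param archetype_ids ids of the archetype members; each must resolve to a
#'   member with evidence `verified` or `putative`.
#' @return an object of class `HomologousGroup`.
#' @export
homologous_group <- function(name, members, archetype_ids) {
  validate_sequence_set(members)
  archetype_ids <- as.character(archetype_ids)
  if (length(archetype_ids) == 0) stop("archetype_ids must be non-empty")
  miss <- setdiff(archetype_ids, members$id)
  if (length(miss) > 0)
    stop("archetype id(s) not among members: ", paste(miss, collapse = ", "))
  ev <- members$evidence[match(archetype_ids, members$id)]
  if (!all(ev %in% c("verified", "putative")))
    stop("archetypes must have evidence verified or putative: ",
         paste(archetype_ids[!ev %in% c("verified", "putative")], collapse = ", "))
  structure(list(name = as.character(name), members = members,
                 archetype_ids = archetype_ids),
            class = "HomologousGroup")
}

#' @export
print.HomologousGroup <- function(x, ...) {
  cat(sprintf("HomologousGroup '%s': %d members (%d archetypes)\n",
              x$name, nrow(x$members), length(x$archetype_ids)))
  invisible(x)
}

# ids of verified archetypes of a group
verified_ids <- function(group) {
  m <- group$members
  m$id[m$id %in% group$archetype_ids & m$evidence == "verified"]
}

#' Construct a protein multiple alignment
#'
#' @param rows named character vector of equal-length gapped residue strings.
#' @return an object of class `ProteinAlignment`.
#' @export
protein_alignment <- function(rows) {
  rows <- vapply(rows, toupper, character(1))
  if (length(rows) > 0 && length(unique(nchar(rows))) != 1)
    stop("alignment rows must have equal length")
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by sequence id")
  if (anyDuplicated(names(rows))) stop("duplicate row ids in alignment")
  structure(rows, class = "ProteinAlignment")
}

#' @export
print.ProteinAlignment <- function(x, ...) {
  cat(sprintf("ProteinAlignment: %d rows x %d columns\n", length(x),
              if (length(x)) nchar(x[[1]]) else 0L))
  invisible(x)
}

#' Remove gaps from an alignment row
#' @param row a gapped residue string.
#' @return the ungapped residues.
#' @export
ungap <- function(row) gsub("[-.]", "", row)

#' Read an aligned FASTA file as a ProteinAlignment
#' @param path path to aligned FASTA.
#' @return a [protein_alignment()].
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  rows <- as.character(aa)
  names(rows) <- sub("\\s.*$", "", names(aa))
  protein_alignment(rows)
}

#' Write a ProteinAlignment as aligned FASTA
#' @param alignment a `ProteinAlignment`.
#' @param path output path.
#' @param wrap line width.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path, wrap = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment)) {
    writeLines(paste0(">", names(alignment)[i]), con)
    s <- unclass(alignment)[[i]]
    starts <- seq(1, nchar(s), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a newick tree
#' @param path path to a newick file.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a tree in newick format
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Function metadata table for an HMM database
#'
#' Maps each HMM name to its hydrocarbon substrate class (`alkane` or
#' `aromatic`) and respiration class (`aerobic` or `anaerobic`), used to group
#' annotation summaries.
#'
#' @param hmm_name character vector of HMM names (unique).
#' @param substrate `"alkane"` or `"aromatic"` per HMM.
#' @param respiration `"aerobic"` or `"anaerobic"` per HMM.
#' @param note optional free-text pathway note.
#' @return a data frame of class `FunctionMetadata`.
#' @export
function_metadata <- function(hmm_name, substrate, respiration, note = "") {
  if (anyDuplicated(hmm_name)) stop("duplicate hmm_name in metadata")
  if (!all(substrate %in% c("alkane", "aromatic")))
    stop("substrate must be 'alkane' or 'aromatic'")
  if (!all(respiration %in% c("aerobic", "anaerobic")))
    stop("respiration must be 'aerobic' or 'anaerobic'")
  x <- data.frame(hmm_name = as.character(hmm_name),
                  substrate = substrate, respiration = respiration,
                  note = rep_len(as.character(note), length(hmm_name)),
                  stringsAsFactors = FALSE)
  class(x) <- c("FunctionMetadata", "data.frame")
  x
}
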