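# End-to-end orchestration: build an HMM database from labeled archetypes and
# a homolog database, and annotate protein samples with a cutoff-bearing
# database. Each stage's intermediates are persisted into the run directory
# and a manifest records parameters so runs are reproducible bit-exactly.

default_build_config <- function() {
  list(archetypes = NULL, database = NULL, out_dir = NULL,
       archetype_group_identity = 0.20, grouping_alignment = "local",
       min_qcov = 0.70, max_evalue = 1e-4, derep_cluster_identity = 0.98,
       max_group_size = 5000, identity_ladder = c(0.50, 0.70, 0.90, 0.98),
       pseudocount_weight = 1.0, background = "robinson", epsilon = 0.1,
       singleton_group_overrides = list(), seed_overrides = list(),
       cutoff_overrides = list())
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return named list of configuration values merged over the defaults.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_build_config(), cfg)
}

validate_build_config <- function(config) {
  config <- utils::modifyList(default_build_config(), config)
  for (field in c("archetypes", "database", "out_dir")) {
    if (is.null(config[[field]]))
      stop("config error: '", field, "' is required", call. = FALSE)
  }
  for (field in c("archetypes", "database")) {
    if (!file.exists(config[[field]]))
      stop("config error: no such file: ", config[[field]], call. = FALSE)
  }
  config
}

#' Build a calibrated HMM database from archetypes and a homolog database
#'
#' Runs the full workflow: archetype grouping, homolog recruitment,
#' dereplication/clustering, nested phylogenetic pruning, seed realignment,
#' HMM construction and trusted/noise cutoff calibration. Every intermediate
#' (groups, seed alignments, trees, cluster tables, per-HMM diagnostics and
#' score plots) is written under `out_dir`, together with a manifest of all
#' parameters.
#'
#' @param config named list (see [read_config()]) or path to a YAML file.
#'   Required fields: `archetypes` and `database` (protein FASTA paths,
#'   archetypes labeled with the `[evidence=...;function=...]` dialect) and
#'   `out_dir`.
#' @return invisible list with `hmms` (calibrated models), `groups`,
#'   `seeds`, and the database path `hmm_file`.
#' @export
run_build <- function(config) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_build_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  bg <- background_frequencies(config$background)

  archetypes <- read_fasta(config$archetypes)
  if (nrow(archetypes) == 0)
    stop("data error: no archetype sequences in ", config$archetypes,
         call. = FALSE)
  database <- read_fasta(config$database)

  stage <- function(name, group_name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for group '", group_name, "': ",
           conditionMessage(e), call. = FALSE))
  }

  groups <- group_archetypes(archetypes,
                             threshold = config$archetype_group_identity,
                             grouping_alignment = config$grouping_alignment)
  hmms <- list()
  seeds <- list()
  full_groups <- list()
  for (g in groups) {
    gname <- g$name
    expanded <- stage("recruit", gname,
                      recruit_homologs(g, database,
                                       min_qcov = config$min_qcov,
                                       max_evalue = config$max_evalue))
    compacted <- stage("compact", gname,
                       compact_recruits(expanded,
                                        cluster_identity =
                                          config$derep_cluster_identity))
    full_groups[[gname]] <- compacted
    override <- config$seed_overrides[[gname]]
    seed <- stage("prune", gname,
                  nested_prune(compacted,
                               prune_config(config$max_group_size,
                                            config$identity_ladder),
                               run_dir = file.path(out, "prune"),
                               override = override))
    seeds[[gname]] <- seed
    write_fasta(seed, file.path(out, paste0(gname, "_seed.faa")))
    aln <- stage("align", gname, progressive_align(seed))
    write_alignment(aln, file.path(out, paste0(gname, "_seed.aln")))
    hmm <- stage("build_hmm", gname,
                 build_hmm(aln, gname,
                           pseudocount_weight = config$pseudocount_weight,
                           background = bg))
    dists <- stage("calibrate", gname,
                   score_distributions(hmm, compacted, seed$id))
    pair <- if (!is.null(config$cutoff_overrides[[gname]])) {
      ov <- config$cutoff_overrides[[gname]]
      cutoff_pair(ov$trusted, ov$noise)
    } else choose_cutoffs(dists$verified, dists$offtarget,
                          epsilon = config$epsilon)
    hmm <- attach_cutoffs(hmm, pair)
    write_tsv_report(calibration_table(dists),
                     file.path(out, paste0(gname, "_scores.tsv")))
    plot_score_distributions(dists, pair,
                             file.path(out, paste0(gname, "_scores.png")),
                             title = gname)
    hmms[[gname]] <- hmm
  }
  hmm_file <- file.path(out, "database.hmm")
  write_hmmer3(hmms, hmm_file)

  manifest <- c(list(package = "hmmforge",
                     version = as.character(utils::packageVersion("hmmforge")),
                     n_groups = length(groups), n_hmms = length(hmms)),
                config[!vapply(config, is.null, logical(1))])
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(list(hmms = hmms, groups = full_groups, seeds = seeds,
                 hmm_file = hmm_file))
}

#' Annotate protein samples with a calibrated HMM database
#'
#' @param config named list or YAML path with fields: `hmms` (a `.hmm` file
#'   with TC/NC lines), `proteins` (named list or vector of protein FASTA
#'   paths, or a single path), `out_dir`, optional `metadata` (TSV with
#'   hmm_name, substrate, respiration columns), optional `mode`
#'   (`cutoff`/`evalue`), optional `total_genes` (named list per sample).
#' @return invisible list with per-sample annotation records and, when
#'   metadata is given, the summary table.
#' @export
run_annotate <- function(config) {
  if (is.character(config)) config <- read_config(config)
  for (field in c("hmms", "proteins", "out_dir"))
    if (is.null(config[[field]]))
      stop("config error: '", field, "' is required", call. = FALSE)
  if (length(config$proteins) == 0)
    stop("config error: empty sample list", call. = FALSE)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  mode <- if (is.null(config$mode)) "cutoff" else config$mode
  database <- read_hmmer3(config$hmms)
  samples <- config$proteins
  if (is.null(names(samples)))
    names(samples) <- tools::file_path_sans_ext(basename(unlist(samples)))
  records <- list()
  for (s in names(samples)) {
    proteins <- read_fasta(samples[[s]])
    recs <- annotate_sample(proteins, database, mode = mode)
    write_tsv_report(recs, file.path(out, paste0(s, "_annotations.tsv")))
    counts <- if (mode == "cutoff") table(recs$tier)
              else c(hits = nrow(recs))
    message(sprintf("[%s] %s", s,
                    paste(names(counts), counts, sep = "=", collapse = " ")))
    records[[s]] <- recs
  }
  summary_tbl <- NULL
  if (!is.null(config$metadata) && mode == "cutoff") {
    md <- utils::read.delim(config$metadata, stringsAsFactors = FALSE)
    metadata <- function_metadata(md$hmm_name, md$substrate, md$respiration,
                                  if (!is.null(md$note)) md$note else "")
    totals <- if (!is.null(config$total_genes))
      unlist(config$total_genes) else NULL
    summary_tbl <- summary_matrix(records, metadata,
                                  hmm_names = names(database),
                                  total_genes = totals)
    write_tsv_report(summary_tbl, file.path(out, "summary.tsv"))
  }
  invisible(list(records = records, summary = summary_tbl))
}
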