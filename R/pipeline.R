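#' Run the full barcode delineation pipeline
#'
#' Executes, in order: FASTA reading, quality control, K2P distance matrix
#' (records in undefined pairs dropped with a logged warning),
#' neighbor-joining tree with optional column-bootstrap supports, pair
#' partitioning, barcoding-gap thresholds, anomaly flags, species
#' delineation and — when a database-similarity table is supplied — match
#' classification resolved against the flags. Outputs are written under
#' `out_dir`: `tree.nwk`, `distances.tsv`, `species_status.tsv`,
#' `flags.tsv`, `summary.json` and `pipeline.log`. Identical inputs, seed
#' and configuration give identical outputs; partial outputs are removed on
#' failure.
#'
#' @param input path to a labelled, aligned FASTA
#'   (`accession|Genus species` headers).
#' @param out_dir output directory (created if missing).
#' @param matches optional path to a database-similarity TSV (see
#'   [read_match_table]).
#' @param bootstrap bootstrap replicates for clade supports (default 1000;
#'   0 skips supports).
#' @param seed integer seed driving every stochastic step.
#' @param min_length QC minimum ungapped length (strict `>`; default 600).
#' @param check_frame apply the reading-frame QC check (default `TRUE`;
#'   disable for non-coding or simulated input).
#' @param deletion `"pairwise"` or `"complete"` site deletion for
#'   distances.
#' @param trim threshold trim mode, `"none"` (default) or `"midgap"`
#'   (see [compute_thresholds]); enable `"midgap"` when screening for
#'   deep-divergent or mislabelled records.
#' @return Invisibly, a list with every intermediate product (`records`,
#'   `qc`, `dm`, `tree`, `partition`, `thresholds`, `delineation`,
#'   `classification`, `summary`).
#' @export
run_pipeline <- function(input, out_dir, matches = NULL, bootstrap = 1000,
                         seed = 1, min_length = 600, check_frame = TRUE,
                         deletion = c("pairwise", "complete"),
                         trim = c("none", "midgap")) {
  deletion <- match.arg(deletion)
  trim <- match.arg(trim)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  made <- character(0)
  ok <- FALSE
  on.exit({
    close(log_con)
    if (!ok) unlink(c(made, log_path))
  })
  say <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  emit <- function(fname, writer) {
    p <- file.path(out_dir, fname)
    writer(p)
    made <<- c(made, p)
    p
  }

  set.seed(seed)
  say("stage: read (", input, ")")
  records <- stage("read", read_fasta(input))
  say("  ", nrow(records), " records")

  say("stage: qc (min ungapped length > ", min_length, ")")
  qc <- stage("qc", qc_filter(records, min_length = min_length,
                              check_frame = check_frame))
  for (acc in names(qc$rejected))
    say("  dropped record ", acc, ": ", qc$rejected[acc])
  records <- qc_keep(records, qc)

  say("stage: distances (", deletion, " deletion)")
  dm <- stage("distances", {
    aligned_length(records)
    suppressWarnings(distance_matrix(records, deletion = deletion))
  })
  if (nrow(dm$undefined_pairs) > 0L) {
    dd <- drop_undefined(dm)
    for (acc in dd$dropped)
      say("  dropped record ", acc, ": undefined K2P distances")
    dm <- dd$dm
    records <- records[records$accession %in% dm$labels, , drop = FALSE]
  }

  say("stage: nj tree (bootstrap ", bootstrap, ")")
  tree <- stage("nj", if (bootstrap > 0)
    bootstrap_supports(records, replicates = bootstrap,
                       deletion = deletion)
    else nj_tree(dm))
  emit("tree.nwk", function(p) write_newick(tree, p))
  emit("distances.tsv", function(p) write_distance_tsv(dm, p))

  say("stage: delineation (trim ", trim, ")")
  partition <- stage("partition", partition_pairs(dm, records))
  species <- unique(records$species)
  cohesion <- vapply(species, function(s)
    is_cohesive(tree, s, records), logical(1))
  thresholds <- stage("thresholds",
                      compute_thresholds(partition, cohesion, trim = trim))
  delineation <- stage("delineate",
                       delineate(records, dm, tree, thresholds))
  flags <- attr(delineation, "flags")
  emit("species_status.tsv", function(p)
    utils::write.table(delineation, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))
  emit("flags.tsv", function(p)
    utils::write.table(flags, p, sep = "\t", quote = FALSE,
                       row.names = FALSE))

  classification <- NULL
  resolved <- NULL
  if (!is.null(matches)) {
    say("stage: match classification (", matches, ")")
    tab <- stage("matches", read_match_table(matches))
    classification <- stage("classify", classify_matches(tab))
    resolved <- stage("resolve", resolve_with_flags(classification, flags))
  }

  summary <- list(
    schema = "barcodeGap-summary-1",
    seed = seed,
    n_records = nrow(records),
    n_species = length(species),
    n_rejected_qc = length(qc$rejected),
    max_conspecific = round(thresholds$max_conspecific, 3),
    min_congeneric = round(thresholds$min_congeneric, 3),
    gap_fold = round(thresholds$gap_fold, 2),
    n_flags = nrow(flags),
    delineated = sum(delineation$status == "delineated"),
    ambiguous = sum(delineation$status == "ambiguous"),
    species_status = stats::setNames(as.list(delineation$status),
                                     delineation$species))
  if (!is.null(resolved)) {
    ids <- identification_summary(resolved)
    summary$match_identified <- ids$identified
    summary$match_inconclusive <- ids$inconclusive
    summary$match_identified_pct <- round(ids$identified_pct, 1)
  }
  emit("summary.json", function(p)
    jsonlite::write_json(summary, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
  say("done")
  ok <- TRUE
  invisible(list(records = records, qc = qc, dm = dm, tree = tree,
                 partition = partition, thresholds = thresholds,
                 delineation = delineation,
                 classification = classification, resolved = resolved,
                 summary = summary))
}

#' Simulate a dataset and write it to disk
#'
#' Thin wrapper over [simulate_dataset] + [write_simulated] that also
#' echoes the configuration as JSON next to the data.
#'
#' @param config a [sim_config].
#' @param out_dir output directory.
#' @param prefix file-name prefix.
#' @return Named character vector of the paths written, invisibly.
#' @export
run_simulate <- function(config, out_dir, prefix = "synthetic") {
  sim <- simulate_dataset(config)
  paths <- write_simulated(sim, out_dir, prefix = prefix)
  cfg_path <- file.path(out_dir, paste0(prefix, "_config.json"))
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(c(paths, config = cfg_path))
}
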