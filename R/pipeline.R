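# Orchestration: wire normalisation -> differential expression -> target
# prioritisation -> drug repurposing -> report, with a declarative config,
# stage-named failures and fully reproducible outputs.

#' Assemble a pipeline run configuration
#'
#' @param inputs Either a bundle directory (as written by
#'   [make_fixture_bundle()] / [make_engineered_bundle()]) or a named list
#'   of file paths with elements `ct_table`, `escsc_genes`,
#'   `interactions`, `associations`, `licence`, `registry`, `redo`,
#'   `edges`.
#' @param out_dir Output directory for all artifacts.
#' @param q_cut Q-value (FDR) threshold for significance (default 0.1).
#' @param dct_cut Minimum absolute delta-Ct group difference, cycles
#'   (default 2).
#' @param ct_detect Detection cut-off on the Ct scale (default 35).
#' @param ct_high High-expression cut-off (default 25).
#' @param exclude_mode Ct-exclusion rule: undetected in `"both"` groups
#'   (default) or in the `"reference"` (2D) group.
#' @param norm_scope Global-mean scope, `"joint"` across a sample's card
#'   platforms (default) or `"per_card"`.
#' @param disease Disease term for polypharmacology expansion.
#' @param min_clique Minimum size for mutually-interacting cores.
#' @return List of class `run_config`.
#' @export
run_config <- function(inputs, out_dir, q_cut = 0.1, dct_cut = 2,
                       ct_detect = CT_DETECT, ct_high = CT_HIGH,
                       exclude_mode = c("both", "reference"),
                       norm_scope = c("joint", "per_card"),
                       disease = "cancer", min_clique = 2) {
  stopifnot(q_cut > 0, dct_cut > 0, ct_detect > 0, ct_high > 0)
  if (is.character(inputs) && length(inputs) == 1 && dir.exists(inputs))
    inputs <- as.list(setNames(file.path(inputs, BUNDLE_FILES),
                               names(BUNDLE_FILES)))
  stopifnot(is.list(inputs))
  missing <- setdiff(names(BUNDLE_FILES), names(inputs))
  if (length(missing))
    stop("run_config inputs missing: ", paste(missing, collapse = ", "))
  structure(list(inputs = inputs, out_dir = out_dir, q_cut = q_cut,
                 dct_cut = dct_cut, ct_detect = ct_detect,
                 ct_high = ct_high,
                 exclude_mode = match.arg(exclude_mode),
                 norm_scope = match.arg(norm_scope), disease = disease,
                 min_clique = min_clique),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order -- Ct ingestion, global-mean
#' normalisation, moderated differential expression with the Q/delta-Ct/Ct
#' significance rule, volcano and detection-set summaries, target
#' prioritisation with network degrees, and the drug-repurposing candidate
#' report -- writing each artifact to `cfg$out_dir` along with an echo of
#' the effective configuration. Every stage failure aborts with an error
#' naming the stage.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory `de`, `volcano`,
#'   `detection`, `targets`, `report` and `summary` objects plus the
#'   `paths` written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cfg$inputs))
    if (!file.exists(cfg$inputs[[nm]]))
      stop("stage 'inputs': missing input file '", nm, "': ",
           cfg$inputs[[nm]], call. = FALSE)

  cards <- stage("ingest", read_ct_table(cfg$inputs$ct_table))
  dctm <- stage("normalise", build_dct_matrix(cards, scope = cfg$norm_scope))
  de <- stage("differential_expression", {
    groups <- setNames(dctm$samples$condition, dctm$samples$sample_id)
    res <- moderated_de(dctm$dct, groups)
    apply_significance_filter(res, group_mean_ct(dctm),
                              q_cut = cfg$q_cut, dct_cut = cfg$dct_cut,
                              ct_detect = cfg$ct_detect,
                              exclude_mode = cfg$exclude_mode)
  })
  volcano <- stage("volcano",
                   volcano_table(de, q_cut = cfg$q_cut,
                                 dct_cut = cfg$dct_cut))
  detection <- stage("detection_sets", {
    cm <- group_mean_ct(dctm)
    detection_set_analysis(setNames(classify_tier(cm$ct_a), cm$gene),
                           setNames(classify_tier(cm$ct_b), cm$gene))
  })
  targets <- stage("targets", {
    de_up <- de$gene[de$significant & de$diff > 0]
    merge_target_sources(de_up, read_gene_list(cfg$inputs$escsc_genes))
  })
  edges <- stage("edges", read_edge_list(cfg$inputs$edges))
  report <- stage("repurpose", {
    build_candidate_table(
      targets,
      read_interaction_table(cfg$inputs$interactions),
      licence = read_licence_list(cfg$inputs$licence),
      registry = read_trial_registry(cfg$inputs$registry),
      redo = read_redo_table(cfg$inputs$redo),
      assoc = read_association_table(cfg$inputs$associations),
      disease = cfg$disease)
  })
  targets <- report$targets
  targets$degree <- vapply(targets$symbol, function(g)
    target_degree(edges, g, targets$symbol), 0L)
  report$targets <- targets
  cores <- stage("network_cores",
                 mutually_interacting_core(edges, targets$symbol,
                                           k = cfg$min_clique))

  summary <- c(report$summary, list(
    n_genes_panel = nrow(dctm$dct),
    n_samples = ncol(dctm$dct),
    n_significant = sum(de$significant),
    n_increased_3d = sum(volcano$category == "increased_3d"),
    n_decreased_3d = sum(volcano$category == "decreased_3d"),
    detection_percentages = as.list(detection$percentages),
    max_target_degree = if (nrow(targets)) max(targets$degree) else 0,
    largest_core = if (length(cores)) cores[[1]] else character(0)))

  paths <- stage("write_outputs", {
    p <- write_candidate_report(report, cfg$out_dir)
    p["dct"] <- write_dct_matrix(dctm, file.path(cfg$out_dir,
                                                 "dct_matrix.tsv"))
    p["de"] <- file.path(cfg$out_dir, "de_results.tsv")
    write.table(de, p["de"], sep = "\t", quote = FALSE, row.names = FALSE)
    p["volcano"] <- file.path(cfg$out_dir, "volcano.tsv")
    write.table(volcano, p["volcano"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    p["detection"] <- file.path(cfg$out_dir, "detection_summary.json")
    jsonlite::write_json(
      c(lapply(unclass(detection)[c("shared_detected", "shared_high",
                                    "not_detected_both",
                                    "unique_undetected_a",
                                    "unique_undetected_b", "panel_size")],
               identity),
        list(percentages = as.list(detection$percentages))),
      p["detection"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p["summary"] <- file.path(cfg$out_dir, "summary.json")
    jsonlite::write_json(summary, p["summary"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    p["config"] <- file.path(cfg$out_dir, "config.json")
    cfg_echo <- unclass(cfg)
    cfg_echo$inputs <- lapply(cfg_echo$inputs, as.character)
    jsonlite::write_json(cfg_echo, p["config"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    p
  })
  invisible(list(de = de, volcano = volcano, detection = detection,
                 targets = targets, report = report, cores = cores,
                 summary = summary, paths = paths))
}

#' Print the headline counts of a finished run
#'
#' Reads `summary.json` from an output directory (or takes the list
#' returned by [run_pipeline()]) and prints the headline counts: targets,
#' druggable targets, candidate drugs and the cancer/non-cancer split,
#' plus the top-scoring drug per druggable target.
#'
#' @param x Output directory or `run_pipeline()` result.
#' @return Invisibly, the summary list.
#' @export
summarise_run <- function(x) {
  s <- if (is.character(x)) {
    path <- file.path(x, "summary.json")
    if (!file.exists(path)) stop("no summary.json under ", x)
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else x$summary
  cat(sprintf("Prioritised targets: %d\n", s$n_targets))
  cat(sprintf("Targets with >=1 candidate drug: %d/%d (%d%%)\n",
              s$n_targets_with_drug, s$n_targets,
              as.integer(s$pct_targets_with_drug)))
  cat(sprintf("Candidate drugs: %d (cancer %d / non-cancer %d)\n",
              s$n_drugs, s$n_cancer_drugs, s$n_non_cancer_drugs))
  cat(sprintf("Drugs with oncology trial activity: %d\n",
              s$n_drugs_in_oncology_trials))
  top <- s$top_drug_per_target
  top <- top[!vapply(top, function(v) is.null(v) || is.na(v), TRUE)]
  if (length(top))
    cat("Top drug by interaction score per target:\n",
        paste(sprintf("  %s: %s", names(top), unlist(top)),
              collapse = "\n"), "\n", sep = "")
  invisible(s)
}
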