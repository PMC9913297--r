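# Drug-repurposing stage: ingestion of database snapshots (drug-gene
# interactions, target-disease associations, cancer-drug licences,
# clinical-trial registry extracts, ReDO evidence), interaction scoring,
# polypharmacology expansion, trial aggregation, support scoring and the
# Table-2-shaped candidate report.

PHASE_LEVELS <- c("Other", "Phase 1", "Phase 1/2", "Phase 2", "Phase 2/3",
                  "Phase 3", "Phase 4")
REDO_EVIDENCE <- c("in_vitro", "in_vivo", "case_report", "observational",
                   "trial_data")

#' Read a drug-gene interaction snapshot
#'
#' TSV with columns `drug`, `gene`, `publication_count`, `source_count`.
#' Drug names are case-folded, gene symbols upper-cased; duplicate
#' (drug, gene) pairs are an error.
#'
#' @param path Path to the interaction TSV.
#' @return Data frame `drug`, `gene`, `publication_count`, `source_count`.
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) stop("interaction table not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("drug", "gene", "publication_count", "source_count")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("interaction table missing columns: ",
         paste(missing, collapse = ", "))
  x$drug <- tolower(trimws(x$drug)); x$gene <- toupper(trimws(x$gene))
  if (any(x$publication_count < 0) || any(x$source_count < 0))
    stop("publication/source counts must be non-negative")
  key <- paste(x$drug, x$gene)
  if (anyDuplicated(key))
    stop("duplicate drug-gene pair: ", key[duplicated(key)][1])
  x[need]
}

#' Compute interaction scores for a drug-gene table
#'
#' For each drug-gene edge the score is
#' `(publication_count + source_count) *
#'  (average gene partners over all drugs / gene partners of this drug) *
#'  (average drug partners over all genes / drug partners of this gene)`,
#' so promiscuous drugs and heavily drugged genes are down-weighted.
#' Averages are taken over the full table by default; `scope_genes`
#' restricts the table to a gene slice before computing anything.
#'
#' @param table Interaction data frame (see [read_interaction_table()]).
#' @param scope_genes Optional gene subset defining the scoring slice.
#' @return The table with an `interaction_score` column appended.
#' @export
score_interactions <- function(table, scope_genes = NULL) {
  stopifnot(nrow(table) > 0)
  if (!is.null(scope_genes))
    table <- table[table$gene %in% toupper(scope_genes), , drop = FALSE]
  if (!nrow(table)) stop("no interactions left after gene slicing")
  genes_per_drug <- table(table$drug)
  drugs_per_gene <- table(table$gene)
  gpd <- as.numeric(genes_per_drug[table$drug])
  dpg <- as.numeric(drugs_per_gene[table$gene])
  if (any(gpd == 0) || any(dpg == 0))
    stop("edge with zero partner count; interaction table is inconsistent")
  table$interaction_score <-
    (table$publication_count + table$source_count) *
    (mean(genes_per_drug) / gpd) *
    (mean(drugs_per_gene) / dpg)
  table
}

#' Interaction score of a single drug-gene edge
#'
#' @param drug,gene Edge to score (must be present in `table`).
#' @param table Interaction data frame.
#' @param scope_genes Optional scoring slice, as in [score_interactions()].
#' @return Numeric score.
#' @export
interaction_score <- function(drug, gene, table, scope_genes = NULL) {
  scored <- score_interactions(table, scope_genes)
  hit <- scored$drug == tolower(drug) & scored$gene == toupper(gene)
  if (!any(hit)) stop("edge not present in table: ", drug, " - ", gene)
  scored$interaction_score[hit]
}

#' Read a target-disease association snapshot
#'
#' TSV with columns `gene`, `disease`, `score` (association strength in
#' `[0, 1]`).
#'
#' @param path Path to the association TSV.
#' @return Data frame `gene`, `disease`, `score`.
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) stop("association table not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene", "disease", "score"), names(x))
  if (length(missing))
    stop("association table missing columns: ",
         paste(missing, collapse = ", "))
  x$gene <- toupper(trimws(x$gene)); x$disease <- tolower(trimws(x$disease))
  if (any(x$score < 0 | x$score > 1))
    stop("association scores must lie in [0, 1]")
  x[c("gene", "disease", "score")]
}

#' Polypharmacology expansion of a drug's target list
#'
#' Returns every gene the drug interacts with that carries an association
#' record for the given disease, sorted by association score (descending;
#' alphabetical within ties).
#'
#' @param drug Drug name.
#' @param table Interaction data frame.
#' @param assoc Association data frame (see [read_association_table()]).
#' @param disease Disease term (case-insensitive exact match).
#' @return Character vector of gene symbols (possibly empty).
#' @export
expand_polypharmacology <- function(drug, table, assoc, disease) {
  if (!nzchar(disease)) stop("disease term must be non-empty")
  genes <- table$gene[table$drug == tolower(drug)]
  hits <- assoc[assoc$gene %in% genes & assoc$disease == tolower(disease), ]
  hits <- hits[order(-hits$score, hits$gene), ]
  hits$gene
}

#' Read a cancer-drug licence list
#'
#' One drug per line; names are case-folded.
#'
#' @param path Path to the licence list.
#' @return Character vector of licensed drug names.
#' @export
read_licence_list <- function(path) {
  if (!file.exists(path)) stop("licence list not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  tolower(x[nzchar(x) & !startsWith(x, "#")])
}

#' Is a drug a licensed cancer drug?
#'
#' Case-insensitive membership in the licence table.
#'
#' @param drug Drug name(s).
#' @param licence_table Character vector of licensed drug names.
#' @return Logical.
#' @export
classify_cancer_drug <- function(drug, licence_table) {
  tolower(trimws(drug)) %in% tolower(trimws(licence_table))
}

#' Read a clinical-trial registry extract
#'
#' TSV with columns `trial_id`, `drug`, `phase`, `status`, `cancer_type`.
#' Phase literals must be one of `"Other"`, `"Phase 1"`, `"Phase 1/2"`,
#' `"Phase 2"`, `"Phase 2/3"`, `"Phase 3"`, `"Phase 4"`; anything else is
#' a hard error naming the record. An empty `cancer_type` marks a
#' non-oncology trial.
#'
#' @param path Path to the registry TSV.
#' @return Data frame with `phase` as an ordered factor.
#' @export
read_trial_registry <- function(path) {
  if (!file.exists(path)) stop("trial registry not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("trial_id", "drug", "phase", "status", "cancer_type")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("trial registry missing columns: ", paste(missing, collapse = ", "))
  if (any(!nzchar(x$trial_id))) stop("trial records must carry a trial_id")
  x$drug <- tolower(trimws(x$drug))
  bad <- !x$phase %in% PHASE_LEVELS
  if (any(bad))
    stop("malformed trial phase '", x$phase[bad][1], "' in record ",
         x$trial_id[bad][1])
  x$phase <- factor(x$phase, levels = PHASE_LEVELS, ordered = TRUE)
  x[need]
}

#' Aggregate a drug's clinical-trial records
#'
#' Counts trials and builds phase, status and cancer-type histograms plus
#' the maximum trial phase. Phase ordering is
#' Other < Phase 1 < Phase 1/2 < Phase 2 < Phase 2/3 < Phase 3 < Phase 4,
#' so `"Other"` is only the maximum when no numbered phase is recorded.
#'
#' @param drug Drug name.
#' @param registry Registry data frame (see [read_trial_registry()]).
#' @return Object of class `trial_summary`: list with `drug`,
#'   `trial_count`, `max_phase` (character or `NA`), `phase_hist`,
#'   `status_hist`, `cancer_type_hist` (named integer vectors over the
#'   observed categories) and `n_oncology` (records with a non-empty
#'   cancer type).
#' @export
aggregate_trials <- function(drug, registry) {
  recs <- registry[registry$drug == tolower(trimws(drug)), , drop = FALSE]
  n <- nrow(recs)
  hist_of <- function(x) {
    if (!n) return(integer(0))
    tab <- table(x)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out[out > 0]
  }
  phase_tab <- if (n) table(recs$phase) else NULL
  phase_hist <- if (n) {
    keep <- phase_tab > 0
    setNames(as.integer(phase_tab[keep]), names(phase_tab)[keep])
  } else integer(0)
  ct <- ifelse(nzchar(recs$cancer_type), recs$cancer_type, "Not specified")
  structure(list(
    drug = tolower(trimws(drug)),
    trial_count = n,
    max_phase = if (n) as.character(max(recs$phase)) else NA_character_,
    phase_hist = phase_hist,
    status_hist = hist_of(recs$status),
    cancer_type_hist = hist_of(ct),
    n_oncology = sum(nzchar(recs$cancer_type))),
    class = "trial_summary")
}

#' Read a ReDO-style evidence snapshot
#'
#' TSV with a `drug` column and 0/1 columns `in_vitro`, `in_vivo`,
#' `case_report`, `observational`, `trial_data`.
#'
#' @param path Path to the evidence TSV.
#' @return Data frame with logical evidence columns.
#' @export
read_redo_table <- function(path) {
  if (!file.exists(path)) stop("ReDO table not found: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("drug", REDO_EVIDENCE), names(x))
  if (length(missing))
    stop("ReDO table missing columns: ", paste(missing, collapse = ", "))
  x$drug <- tolower(trimws(x$drug))
  for (col in REDO_EVIDENCE) {
    if (!all(x[[col]] %in% c(0, 1, TRUE, FALSE)))
      stop("ReDO column ", col, " must be 0/1")
    x[[col]] <- as.logical(x[[col]])
  }
  x[c("drug", REDO_EVIDENCE)]
}

#' Repurposing support score
#'
#' Plain count of the anticancer evidence categories available for a drug
#' (in vitro, in vivo, case reports, observational data, clinical-trial
#' data), ranging 0-5.
#'
#' @param in_vitro,in_vivo,case_report,observational,trial_data Logicals
#'   (vectorised).
#' @return Integer score(s) in 0-5.
#' @export
support_score <- function(in_vitro = FALSE, in_vivo = FALSE,
                          case_report = FALSE, observational = FALSE,
                          trial_data = FALSE) {
  ev <- cbind(in_vitro, in_vivo, case_report, observational, trial_data)
  if (anyNA(ev)) stop("evidence flags must be defined (no NA)")
  as.integer(rowSums(ev))
}

#' Build the candidate-drug report
#'
#' The core repurposing step: every drug in the interaction snapshot that
#' hits at least one prioritised target gets one row combining its target
#' list (ordered by interaction score), cancer-drug licence flag, trial
#' aggregation, ReDO support score and per-gene interaction scores. The
#' returned report also carries headline summary counts and the target set
#' with `has_drug` filled in.
#'
#' @param targets A `target_set` data frame (see [merge_target_sources()]).
#' @param table Interaction data frame.
#' @param licence Character vector of licensed cancer drugs.
#' @param registry Optional trial-registry data frame.
#' @param redo Optional ReDO evidence data frame.
#' @param assoc Optional association data frame (reserved for
#'   polypharmacology summaries).
#' @param disease Disease term used with `assoc`.
#' @param score_scope `"full"` scores interactions over the whole snapshot
#'   (default); `"slice"` restricts the averages to the target slice.
#' @return Object of class `candidate_report`: list with `candidates`
#'   (data frame), `targets` (updated target set) and `summary` (list of
#'   headline counts).
#' @export
build_candidate_table <- function(targets, table, licence = character(),
                                  registry = NULL, redo = NULL,
                                  assoc = NULL, disease = "cancer",
                                  score_scope = c("full", "slice")) {
  score_scope <- match.arg(score_scope)
  stopifnot(inherits(targets, "data.frame"), nrow(targets) > 0)
  scored <- score_interactions(table,
    scope_genes = if (score_scope == "slice") targets$symbol else NULL)
  hits <- scored[scored$gene %in% targets$symbol, , drop = FALSE]
  targets$has_drug <- targets$symbol %in% hits$gene
  drugs <- sort(unique(hits$drug))
  rows <- lapply(drugs, function(d) {
    h <- hits[hits$drug == d, , drop = FALSE]
    h <- h[order(-h$interaction_score, h$gene), ]
    tr <- if (!is.null(registry)) aggregate_trials(d, registry)
          else aggregate_trials(d, data.frame(
            trial_id = character(), drug = character(),
            phase = factor(character(), levels = PHASE_LEVELS, ordered = TRUE),
            status = character(), cancer_type = character(),
            stringsAsFactors = FALSE))
    sup <- NA_integer_
    if (!is.null(redo)) {
      r <- redo[redo$drug == d, , drop = FALSE]
      if (nrow(r))
        sup <- support_score(r$in_vitro[1], r$in_vivo[1], r$case_report[1],
                             r$observational[1], r$trial_data[1])
    }
    list(drug = d,
         targets = paste(h$gene, collapse = ","),
         n_targets = nrow(h),
         is_cancer_drug = classify_cancer_drug(d, licence),
         trial_count = tr$trial_count,
         max_phase = tr$max_phase,
         n_oncology_trials = tr$n_oncology,
         support_score = sup,
         phase_hist = tr$phase_hist,
         status_hist = tr$status_hist,
         cancer_type_hist = tr$cancer_type_hist,
         interaction_scores = setNames(h$interaction_score, h$gene))
  })
  cand <- data.frame(
    drug = vapply(rows, `[[`, "", "drug"),
    targets = vapply(rows, `[[`, "", "targets"),
    n_targets = vapply(rows, `[[`, 0L, "n_targets"),
    is_cancer_drug = vapply(rows, `[[`, TRUE, "is_cancer_drug"),
    trial_count = vapply(rows, `[[`, 0L, "trial_count"),
    max_phase = vapply(rows, `[[`, "", "max_phase"),
    n_oncology_trials = vapply(rows, `[[`, 0L, "n_oncology_trials"),
    support_score = vapply(rows, `[[`, 0L, "support_score"),
    stringsAsFactors = FALSE, row.names = NULL)
  cand$phase_hist <- lapply(rows, `[[`, "phase_hist")
  cand$status_hist <- lapply(rows, `[[`, "status_hist")
  cand$cancer_type_hist <- lapply(rows, `[[`, "cancer_type_hist")
  cand$interaction_scores <- lapply(rows, `[[`, "interaction_scores")
  cand <- cand[order(-cand$is_cancer_drug, cand$drug), , drop = FALSE]
  rownames(cand) <- NULL
  drugs_per_target <- vapply(targets$symbol, function(g)
    length(unique(hits$drug[hits$gene == g])), 0L)
  n_t <- nrow(targets); n_with <- sum(targets$has_drug)
  top_drug <- vapply(targets$symbol, function(g) {
    h <- hits[hits$gene == g, , drop = FALSE]
    if (!nrow(h)) return(NA_character_)
    h$drug[order(-h$interaction_score, h$drug)][1]
  }, "")
  summary <- list(
    n_targets = n_t,
    n_targets_with_drug = n_with,
    pct_targets_with_drug = as.numeric(round_half_up(100 * n_with / n_t)),
    n_drugs = nrow(cand),
    n_cancer_drugs = sum(cand$is_cancer_drug),
    n_non_cancer_drugs = sum(!cand$is_cancer_drug),
    n_drugs_in_oncology_trials = sum(cand$n_oncology_trials > 0),
    drugs_per_target = as.list(drugs_per_target),
    top_drug_per_target = as.list(top_drug))
  structure(list(candidates = cand, targets = targets, summary = summary),
            class = "candidate_report")
}

format_hist <- function(h) {
  if (!length(h)) return("")
  paste(sprintf("%s (%d)", names(h), h), collapse = "; ")
}

#' Write a candidate report to disk
#'
#' Writes `candidates.tsv` (histograms flattened to
#' `"label (count); ..."` strings), `targets.tsv` and `summary.json`.
#'
#' @param report A `candidate_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_candidate_report <- function(report, dir) {
  stopifnot(inherits(report, "candidate_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cand <- report$candidates
  flat <- cand[!vapply(cand, is.list, TRUE)]
  flat$phase_hist <- vapply(cand$phase_hist, format_hist, "")
  flat$status_hist <- vapply(cand$status_hist, format_hist, "")
  flat$cancer_type_hist <- vapply(cand$cancer_type_hist, format_hist, "")
  flat$interaction_scores <- vapply(cand$interaction_scores, function(s)
    paste(sprintf("%s=%.4g", names(s), s), collapse = ";"), "")
  paths <- c(candidates = file.path(dir, "candidates.tsv"),
             targets = file.path(dir, "targets.tsv"),
             summary = file.path(dir, "summary.json"))
  write.table(flat, paths["candidates"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$targets, paths["targets"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(report$summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
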