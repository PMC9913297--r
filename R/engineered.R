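# The engineered reference bundle: a deterministic fixture whose
# end-to-end analysis reproduces the headline structure of the study --
# 21 prioritised targets of which 13 carry at least one candidate drug
# (62%), a hub gene (POU5F1) interacting with 10 of the 13 druggable
# targets, a fully interacting 5-gene core, and trial registries whose
# per-drug counts match the published per-phase histograms.

#' Path to the packaged 21-gene target list
#'
#' Thirteen genuine stemness/chemoresistance symbols plus eight synthetic
#' placeholders (see the file header for the placeholder mechanism).
#'
#' @return File path inside the installed package.
#' @export
target_panel_file <- function() {
  system.file("extdata", "stemness_targets_21_synthetic.txt",
              package = "stemscreen", mustWork = TRUE)
}

#' Path to the packaged per-phase trial-count table
#'
#' Transcribed per-phase clinical-trial counts for six repurposing
#' candidates (temozolomide, sirolimus, propofol, clarithromycin,
#' simvastatin, disulfiram).
#'
#' @return File path inside the installed package.
#' @export
trial_phase_counts_file <- function() {
  system.file("extdata", "trial_phase_counts.tsv",
              package = "stemscreen", mustWork = TRUE)
}

#' Expand a per-phase trial-count table into registry records
#'
#' Turns rows of (drug, phase, n_trials) into one synthetic trial record
#' per counted trial, with deterministic identifiers. Statuses rotate over
#' the standard registry vocabulary and all records are oncology trials.
#'
#' @param counts Data frame with columns `drug`, `phase`, `n_trials`.
#' @return Trial-registry data frame accepted by [aggregate_trials()].
#' @export
expand_phase_counts <- function(counts) {
  stopifnot(all(c("drug", "phase", "n_trials") %in% names(counts)))
  idx <- rep(seq_len(nrow(counts)), counts$n_trials)
  drug <- tolower(counts$drug[idx])
  phase <- counts$phase[idx]
  bad <- !phase %in% PHASE_LEVELS
  if (any(bad)) stop("malformed trial phase: ", phase[bad][1])
  n <- length(idx)
  data.frame(
    trial_id = sprintf("REG%04d", seq_len(n)),
    drug = drug,
    phase = factor(phase, levels = PHASE_LEVELS, ordered = TRUE),
    status = rep_len(c("Recruiting", "Active, not recruiting", "Completed",
                       "Not yet recruiting", "Ongoing"), n),
    cancer_type = rep_len(c("Multiple cancer types", "GI", "Breast", "CNS"),
                          n),
    stringsAsFactors = FALSE)
}

# Drug-gene interaction snapshot for the engineered bundle. Pairs among
# ABCB1/ABCC1/POU5F1/KIT/DNMT3B/GABRB3 follow the published candidate
# table; the remaining druggable targets receive synthetic inhibitors
# (synmol*) so that exactly the 13 named genes carry a drug.
engineered_interactions <- function() {
  pair <- function(drug, genes) data.frame(drug = drug, gene = genes,
                                           stringsAsFactors = FALSE)
  tab <- rbind(
    pair("imatinib", c("KIT", "ABCB1")),
    pair("dasatinib", "KIT"),
    pair("cabozantinib", "KIT"),
    pair("pazopanib", "KIT"),
    pair("decitabine", "DNMT3B"),
    pair("temozolomide", "ABCB1"),
    pair("sirolimus", "ABCB1"),
    pair("propofol", c("ABCB1", "GABRB3")),
    pair("midazolam", c("ABCB1", "GABRB3")),
    pair("clarithromycin", "ABCB1"),
    pair("simvastatin", "ABCB1"),
    pair("disulfiram", "ABCB1"),
    pair("verapamil", c("ABCB1", "ABCC1")),
    pair("cyclosporine", c("ABCB1", "ABCC1")),
    pair("azithromycin", "ABCC1"),
    pair("indomethacin", "ABCC1"),
    pair("allopurinol", "POU5F1"),
    pair("phenytoin", "POU5F1"),
    pair("synmol01", c("CAV1", "ITGB1")),
    pair("synmol02", c("ITGB1", "CD44")),
    pair("synmol03", "CD44"),
    pair("synmol04", "ABCG1"),
    pair("synmol05", c("LIN28A", "LEFTY2")),
    pair("synmol06", "PROM1"),
    pair("synmol07", c("CAV1", "ABCG1")))
  # Deterministic pseudo-counts: vary with position, no RNG involved.
  tab$publication_count <- ((seq_len(nrow(tab)) * 7) %% 11) + 1L
  tab$source_count <- ((seq_len(nrow(tab)) * 3) %% 5) + 1L
  tab
}

engineered_edges <- function() {
  core <- c("POU5F1", "KIT", "CAV1", "ITGB1", "CD44")
  pairs <- t(utils::combn(core, 2))
  clique <- data.frame(a = pairs[, 1], b = pairs[, 2],
                       evidence = "experimental", stringsAsFactors = FALSE)
  spokes <- data.frame(
    a = "POU5F1",
    b = c("ABCB1", "ABCC1", "DNMT3B", "GABRB3", "LIN28A", "LEFTY2"),
    evidence = c("curated", "curated", "textmining", "textmining",
                 "coexpression", "curated"),
    stringsAsFactors = FALSE)
  rbind(clique, spokes)
}

#' Write the engineered reference bundle
#'
#' Fabricates a complete, deterministic input bundle whose analysis
#' reproduces the headline target/drug structure: the 21-gene panel (13
#' druggable), ABCG1 entering the target set through differential
#' expression alone (planted 4-cycle decrease in 3D Ct), a POU5F1 hub of
#' degree 10 and a fully interacting 5-gene core, plus trial registries
#' whose per-drug counts match the packaged per-phase histograms. Only the
#' Ct noise and filler genes depend on the seed.
#'
#' @param dir Output directory.
#' @param seed Root seed for the Ct noise.
#' @return Invisibly, the named vector of written paths.
#' @export
make_engineered_bundle <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  targets21 <- read_gene_list(target_panel_file())
  stopifnot(length(targets21) == 21)
  filler <- sprintf("G%03d", seq_len(140 - length(targets21)))
  cfg <- sim_config(seed = seed, n_genes = 140,
                    genes = c(targets21, filler),
                    n_samples_per_group = 2,
                    effect_genes = c(ABCG1 = -4, LIN28A = -3, LEFTY2 = -3),
                    noise_sd = 0.5, baseline_ct_range = c(22, 32))
  paths <- file.path(dir, BUNDLE_FILES)
  names(paths) <- names(BUNDLE_FILES)
  write_ct_table(simulate_ct_cards(cfg), paths["ct_table"])
  # ABCG1 is deliberately absent: it must be recovered by the DE stage.
  writeLines(setdiff(targets21, "ABCG1"), paths["escsc_genes"])
  interactions <- engineered_interactions()
  write.table(interactions, paths["interactions"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  drugs <- unique(interactions$drug)
  writeLines(c("imatinib", "dasatinib", "cabozantinib", "pazopanib",
               "decitabine", "temozolomide"), paths["licence"])
  counts <- read.delim(trial_phase_counts_file(), stringsAsFactors = FALSE)
  registry <- expand_phase_counts(counts)
  rest <- setdiff(drugs, unique(registry$drug))
  extra <- data.frame(
    trial_id = sprintf("REGX%03d", seq_along(rest)),
    drug = rest,
    phase = factor("Phase 2", levels = PHASE_LEVELS, ordered = TRUE),
    status = "Recruiting",
    cancer_type = rep_len(c("Multiple cancer types", ""), length(rest)),
    stringsAsFactors = FALSE)
  write.table(rbind(registry, extra), paths["registry"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  redo <- data.frame(drug = sort(drugs), stringsAsFactors = FALSE)
  for (i in seq_along(REDO_EVIDENCE))
    redo[[REDO_EVIDENCE[i]]] <-
      as.integer((seq_len(nrow(redo)) + i) %% 2 == 0 | i <= 2)
  write.table(redo, paths["redo"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(engineered_edges(), paths["edges"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  assoc <- data.frame(gene = sort(unique(interactions$gene)),
                      disease = "cancer", stringsAsFactors = FALSE)
  assoc$score <- round(0.95 - 0.04 * (seq_len(nrow(assoc)) - 1), 2)
  write.table(assoc, paths["associations"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(c("# stemscreen engineered reference bundle",
               sprintf("seed: %s", seed),
               "files:",
               sprintf("  %s: %s", names(BUNDLE_FILES), BUNDLE_FILES)),
             file.path(dir, "MANIFEST"))
  invisible(paths)
}
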