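# Synthetic-data generators: fabricate every input the pipeline consumes
# (Ct cards, gene lists, drug-gene interaction snapshots, trial-registry
# extracts, ReDO evidence, association tables, edge lists) with the
# statistical structure the analysis assumes. All generators are pure
# functions of (config, seed) via a fixed stream-splitting scheme.

#' Simulation configuration
#'
#' Bundles all generator parameters. The defaults mirror the study
#' conditions the analysis is built for: a 140-gene panel (excluding
#' endogenous controls) measured in two independent experiments per
#' condition, Ct noise of half a cycle, and a drug-gene snapshot with 21
#' candidate target genes.
#'
#' @param seed Root seed; fixes all randomness end-to-end.
#' @param n_genes Panel size (non-control genes).
#' @param n_samples_per_group Replicates per condition (2D and 3D).
#' @param effect_genes Named numeric vector: planted delta-delta-Ct
#'   (cycles) added to the 3D group. Negative values lower the 3D Ct,
#'   i.e. increase expression in spheroids.
#' @param noise_sd Gaussian Ct noise, cycles (> 0).
#' @param baseline_ct_range Uniform range for per-gene baseline Ct.
#' @param n_drugs,n_gene_targets Size of the drug-gene snapshot.
#' @param edge_density Probability that a drug-gene pair interacts.
#' @param trial_rate Mean trials per drug (Poisson).
#' @param genes Optional explicit gene panel (length `n_genes`).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 140, n_samples_per_group = 2,
                       effect_genes = numeric(0), noise_sd = 0.5,
                       baseline_ct_range = c(22, 34), n_drugs = 60,
                       n_gene_targets = 21, edge_density = 0.15,
                       trial_rate = 3, genes = NULL) {
  stopifnot(noise_sd > 0, edge_density >= 0, edge_density <= 1,
            trial_rate >= 0, n_genes >= 2, n_samples_per_group >= 1,
            length(baseline_ct_range) == 2,
            baseline_ct_range[1] > 0, baseline_ct_range[2] <= CT_MAX,
            baseline_ct_range[1] <= baseline_ct_range[2])
  if (length(effect_genes) && is.null(names(effect_genes)))
    stop("effect_genes must be a named vector of planted shifts")
  if (!is.null(genes)) {
    genes <- toupper(genes)
    stopifnot(length(genes) == n_genes, !anyDuplicated(genes))
  }
  structure(list(seed = seed, n_genes = n_genes,
                 n_samples_per_group = n_samples_per_group,
                 effect_genes = effect_genes, noise_sd = noise_sd,
                 baseline_ct_range = baseline_ct_range, n_drugs = n_drugs,
                 n_gene_targets = n_gene_targets,
                 edge_density = edge_density, trial_rate = trial_rate,
                 genes = genes),
            class = "sim_config")
}

sim_gene_panel <- function(cfg) {
  cfg$genes %||% sprintf("G%03d", seq_len(cfg$n_genes))
}

#' Simulate Ct array cards for a 2D vs 3D experiment
#'
#' Draws one baseline Ct per gene uniformly over
#' `cfg$baseline_ct_range`, adds the planted effects to the 3D samples
#' and Gaussian noise everywhere, clips values above 40 to 40 (flagged
#' undetected, mirroring ingestion), and splits the panel over the three
#' card platforms.
#'
#' @param cfg A [sim_config()].
#' @return List of [ct_card] objects (one per sample x platform).
#' @export
simulate_ct_cards <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- sim_gene_panel(cfg)
  bad <- setdiff(names(cfg$effect_genes), genes)
  if (length(bad))
    stop("effect genes not in the panel: ", paste(bad, collapse = ", "))
  n <- cfg$n_samples_per_group
  with_stream(cfg$seed, "ct_cards", {
    baseline <- runif(length(genes), cfg$baseline_ct_range[1],
                      cfg$baseline_ct_range[2])
    names(baseline) <- genes
    effect <- setNames(rep(0, length(genes)), genes)
    effect[names(cfg$effect_genes)] <- cfg$effect_genes
    platform <- rep(PLATFORMS, length.out = length(genes))
    cards <- list()
    for (cond in CONDITIONS) {
      for (i in seq_len(n)) {
        ct <- baseline + if (cond == "3D") effect else 0
        ct <- ct + rnorm(length(genes), 0, cfg$noise_sd)
        ct <- pmin(ct, CT_MAX)
        ct <- pmax(ct, 1e-3)
        for (pf in PLATFORMS) {
          sel <- platform == pf
          if (!any(sel)) next
          cards[[length(cards) + 1L]] <- ct_card(
            sample_id = sprintf("%s_%d", cond, i), condition = cond,
            platform = pf, cell_line = "SIM",
            measurements = data.frame(
              gene = genes[sel], ct = unname(ct[sel]),
              detected = unname(ct[sel] <= CT_DETECT),
              is_control = FALSE, stringsAsFactors = FALSE))
        }
      }
    }
    cards
  })
}

#' Write cards back to the long Ct-table format
#'
#' @param cards List of [ct_card] objects.
#' @param path Output TSV path.
#' @export
write_ct_table <- function(cards, path) {
  rows <- do.call(rbind, lapply(cards, function(cc) {
    data.frame(sample = cc$sample_id, condition = cc$condition,
               cell_line = cc$cell_line, platform = cc$platform,
               gene = cc$measurements$gene,
               ct = ifelse(cc$measurements$detected |
                             cc$measurements$ct < CT_MAX,
                           sprintf("%.6f", cc$measurements$ct),
                           "Undetermined"),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a drug-gene interaction snapshot
#'
#' Each drug-gene pair enters independently with probability
#' `cfg$edge_density`; publication counts are geometric, source counts
#' uniform on 1..5. Every drug is guaranteed at least one edge.
#'
#' @param cfg A [sim_config()].
#' @param genes Optional target gene symbols (defaults to
#'   `TG01..TGxx` per `cfg$n_gene_targets`).
#' @return Interaction data frame.
#' @export
simulate_interaction_table <- function(cfg, genes = NULL) {
  stopifnot(inherits(cfg, "sim_config"), cfg$n_drugs >= 1)
  genes <- toupper(genes %||% sprintf("TG%02d", seq_len(cfg$n_gene_targets)))
  drugs <- sprintf("drug%03d", seq_len(cfg$n_drugs))
  with_stream(cfg$seed, "interactions", {
    grid <- expand.grid(drug = drugs, gene = genes,
                        stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < cfg$edge_density
    tab <- grid[keep, , drop = FALSE]
    lonely <- setdiff(drugs, tab$drug)
    if (length(lonely))
      tab <- rbind(tab, data.frame(
        drug = lonely,
        gene = sample(genes, length(lonely), replace = TRUE),
        stringsAsFactors = FALSE))
    tab <- tab[order(tab$drug, tab$gene), , drop = FALSE]
    tab$publication_count <- rgeom(nrow(tab), prob = 0.3)
    tab$source_count <- sample(1:5, nrow(tab), replace = TRUE)
    rownames(tab) <- NULL
    tab
  })
}

TRIAL_STATUSES <- c("Recruiting", "Active, not recruiting", "Completed",
                    "Not yet recruiting", "Ongoing", "Terminated",
                    "Suspended", "Other")
CANCER_TYPES <- c("GI", "Breast", "CNS", "Lung", "Leukaemia", "Lymphoma",
                  "Urological", "Gynaecological", "Head and Neck",
                  "Bone Sarcoma", "Soft-Tissue Sarcoma",
                  "Multiple cancer types", "Other Haem-onc")

#' Simulate a clinical-trial registry extract
#'
#' Per-drug trial counts are Poisson with mean `cfg$trial_rate`; phases,
#' statuses and cancer types are drawn from categorical distributions
#' over the standard registry vocabulary. A quarter of records carry an
#' empty cancer type (non-oncology trials).
#'
#' @param cfg A [sim_config()].
#' @param drugs Character vector of drug names.
#' @return Trial-registry data frame.
#' @export
simulate_trial_registry <- function(cfg, drugs) {
  stopifnot(inherits(cfg, "sim_config"), length(drugs) >= 1)
  drugs <- tolower(drugs)
  with_stream(cfg$seed, "trials", {
    counts <- rpois(length(drugs), cfg$trial_rate)
    total <- sum(counts)
    if (total == 0)
      return(data.frame(trial_id = character(), drug = character(),
                        phase = factor(character(), levels = PHASE_LEVELS,
                                       ordered = TRUE),
                        status = character(), cancer_type = character(),
                        stringsAsFactors = FALSE))
    phase <- sample(PHASE_LEVELS, total, replace = TRUE,
                    prob = c(0.15, 0.25, 0.10, 0.30, 0.02, 0.10, 0.08))
    status <- sample(TRIAL_STATUSES, total, replace = TRUE,
                     prob = c(0.3, 0.15, 0.15, 0.15, 0.1, 0.05, 0.02, 0.08))
    cancer <- ifelse(runif(total) < 0.25, "",
                     sample(CANCER_TYPES, total, replace = TRUE))
    data.frame(trial_id = sprintf("SIM%06d", seq_len(total)),
               drug = rep(drugs, counts),
               phase = factor(phase, levels = PHASE_LEVELS, ordered = TRUE),
               status = status, cancer_type = cancer,
               stringsAsFactors = FALSE)
  })
}

#' Single-cell well occupancy under Poisson seeding
#'
#' Probability that a well seeded at cell density `lambda` contains at
#' most one cell: `P(X <= 1) = exp(-lambda) * (1 + lambda)`.
#'
#' @param lambda Mean cells per well (>= 0, vectorised).
#' @return Probability.
#' @export
poisson_single_cell_occupancy <- function(lambda) {
  if (any(!is.finite(lambda) | lambda < 0))
    stop("lambda must be non-negative")
  exp(-lambda) * (1 + lambda)
}

#' Conditional single-cell probability
#'
#' Companion reading: probability that an occupied well contains exactly
#' one cell, `P(X = 1 | X >= 1)`.
#'
#' @inheritParams poisson_single_cell_occupancy
#' @return Probability.
#' @export
poisson_single_cell_conditional <- function(lambda) {
  if (any(!is.finite(lambda) | lambda < 0))
    stop("lambda must be non-negative")
  ifelse(lambda == 0, 1, lambda * exp(-lambda) / (1 - exp(-lambda)))
}

#' Seeding density achieving a target single-cell probability
#'
#' Solves `exp(-lambda) * (1 + lambda) = p_target` for lambda on the
#' monotone-decreasing branch (lambda > 0).
#'
#' @param p_target Target probability in (0, 1).
#' @return The seeding density lambda.
#' @export
single_cell_lambda <- function(p_target) {
  stopifnot(p_target > 0, p_target < 1)
  uniroot(function(l) poisson_single_cell_occupancy(l) - p_target,
          interval = c(1e-12, 100), tol = 1e-12)$root
}

#' Simulate a target-disease association snapshot
#'
#' @param cfg A [sim_config()].
#' @param genes Gene symbols.
#' @param disease Disease term.
#' @return Association data frame (about 80% of genes covered, scores
#'   uniform on (0, 1)).
#' @export
simulate_associations <- function(cfg, genes, disease = "cancer") {
  with_stream(cfg$seed, "associations", {
    keep <- runif(length(genes)) < 0.8
    data.frame(gene = toupper(genes[keep]), disease = tolower(disease),
               score = round(runif(sum(keep)), 4),
               stringsAsFactors = FALSE)
  })
}

#' Simulate ReDO-style evidence flags
#'
#' @param cfg A [sim_config()].
#' @param drugs Drug names.
#' @return ReDO data frame with five 0/1 evidence columns.
#' @export
simulate_redo <- function(cfg, drugs) {
  with_stream(cfg$seed, "redo", {
    n <- length(drugs)
    out <- data.frame(drug = tolower(drugs), stringsAsFactors = FALSE)
    for (col in REDO_EVIDENCE)
      out[[col]] <- as.integer(runif(n) < 0.5)
    out
  })
}

#' Simulate a protein-association edge list over the target set
#'
#' @param cfg A [sim_config()].
#' @param genes Target gene symbols.
#' @param density Edge probability between distinct genes.
#' @return Edge-list data frame `a`, `b`, `evidence`.
#' @export
simulate_edges <- function(cfg, genes, density = 0.2) {
  genes <- toupper(genes)
  with_stream(cfg$seed, "edges", {
    pairs <- t(utils::combn(genes, 2))
    keep <- runif(nrow(pairs)) < density
    data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
               evidence = sample(EVIDENCE_CHANNELS, sum(keep),
                                 replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

BUNDLE_FILES <- c(ct_table = "ct_table.tsv",
                  escsc_genes = "escsc_genes.txt",
                  interactions = "interactions.tsv",
                  associations = "associations.tsv",
                  licence = "licence.txt",
                  registry = "registry.tsv",
                  redo = "redo.tsv",
                  edges = "edges.tsv")

#' Write a complete fixture bundle of pipeline inputs
#'
#' Fabricates and writes every file the pipeline consumes, in the exact
#' formats the readers expect, plus a MANIFEST describing the layout. The
#' target gene set is the first `cfg$n_gene_targets` panel genes: planted
#' effect genes enter through differential expression (source 2), the
#' rest through the ES-CSC list (source 1).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created; must be writable).
#' @return Invisibly, the named vector of written paths.
#' @export
make_fixture_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create bundle directory: ", dir)
  genes <- sim_gene_panel(cfg)
  target_genes <- genes[seq_len(min(cfg$n_gene_targets, length(genes)))]
  cards <- simulate_ct_cards(cfg)
  paths <- file.path(dir, BUNDLE_FILES)
  names(paths) <- names(BUNDLE_FILES)
  write_ct_table(cards, paths["ct_table"])
  escsc <- setdiff(target_genes, names(cfg$effect_genes))
  writeLines(escsc, paths["escsc_genes"])
  interactions <- simulate_interaction_table(cfg, genes = target_genes)
  write.table(interactions, paths["interactions"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  drugs <- unique(interactions$drug)
  write.table(simulate_associations(cfg, target_genes),
              paths["associations"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  with_stream(cfg$seed, "bundle", {
    writeLines(sort(sample(drugs, max(1, round(length(drugs) * 0.25)))),
               paths["licence"])
  })
  write.table(simulate_trial_registry(cfg, drugs), paths["registry"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(simulate_redo(cfg, drugs), paths["redo"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(simulate_edges(cfg, target_genes), paths["edges"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c("# stemscreen fixture bundle",
               sprintf("seed: %s", cfg$seed),
               "files:",
               sprintf("  %s: %s", names(BUNDLE_FILES), BUNDLE_FILES)),
             file.path(dir, "MANIFEST"))
  invisible(paths)
}
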