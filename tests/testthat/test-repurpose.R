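# Interaction scoring, polypharmacology, licence classification, trial
# aggregation, support scoring and the candidate report.

test_that("a single-edge table scores to publication + source counts", {
  tab <- data.frame(drug = "d1", gene = "G1",
                    publication_count = 3, source_count = 2)
  expect_equal(interaction_score("d1", "G1", tab), 5)
})

test_that("interaction scores match the brute-force oracle", {
  set.seed(3)
  tab <- random_interaction_table(3, 3)
  scored <- score_interactions(tab)
  for (r in seq_len(nrow(tab)))
    expect_equal(scored$interaction_score[r],
                 oracle_interaction_score(tab$drug[r], tab$gene[r], tab),
                 tolerance = 1e-12)
})

test_that("an unrelated edge shifts a score only through the averages", {
  tab <- data.frame(drug = c("d1", "d1", "d2"),
                    gene = c("G1", "G2", "G2"),
                    publication_count = c(4, 1, 2),
                    source_count = c(1, 1, 1))
  before <- interaction_score("d1", "G1", tab)
  # add an edge touching neither d1 nor G1
  tab2 <- rbind(tab, data.frame(drug = "d3", gene = "G3",
                                publication_count = 9, source_count = 9))
  after <- interaction_score("d1", "G1", tab2)
  # hand-recomputed: before = 5 * (1.5/2) * (1.5/1) = 5.625
  expect_equal(before, 5 * (1.5 / 2) * (1.5 / 1))
  # after: avg genes/drug = (2+1+1)/3, avg drugs/gene = (1+2+1)/3
  expect_equal(after, 5 * ((4 / 3) / 2) * ((4 / 3) / 1))
})

test_that("partner-count denominators never grow when a drug is removed", {
  set.seed(19)
  tab <- random_interaction_table(8, 8)
  drop <- unique(tab$drug)[1]
  rest <- tab[tab$drug != drop, ]
  gpd_full <- table(tab$drug)
  dpg_full <- table(tab$gene)
  dpg_rest <- table(rest$gene)
  for (g in names(dpg_rest))
    expect_lte(dpg_rest[[g]], dpg_full[[g]])
})

test_that("polypharmacology expansion filters and orders by association", {
  tab <- data.frame(drug = "d1", gene = c("G1", "G2", "G3"),
                    publication_count = 1, source_count = 1)
  assoc <- data.frame(gene = c("G1", "G3", "G9"), disease = "cancer",
                      score = c(0.4, 0.9, 1.0))
  expect_equal(expand_polypharmacology("d1", tab, assoc, "cancer"),
               c("G3", "G1"))
  expect_equal(expand_polypharmacology("nosuch", tab, assoc, "cancer"),
               character(0))
  ties <- data.frame(gene = c("G2", "G1"), disease = "cancer",
                     score = c(0.5, 0.5))
  expect_equal(expand_polypharmacology("d1", tab, ties, "cancer"),
               c("G1", "G2"))
  expect_error(expand_polypharmacology("d1", tab, assoc, ""), "non-empty")
})

test_that("cancer-drug classification is case-insensitive membership", {
  lic <- c("imatinib", "temozolomide")
  expect_true(classify_cancer_drug("Imatinib", lic))
  expect_true(classify_cancer_drug("imatinib", lic))
  expect_false(classify_cancer_drug("Allopurinol", lic))
})

test_that("trial aggregation reproduces published per-drug counts", {
  counts <- read.delim(trial_phase_counts_file(), stringsAsFactors = FALSE)
  registry <- expand_phase_counts(counts)
  tem <- aggregate_trials("Temozolomide", registry)
  expect_equal(tem$trial_count, 23)
  expect_equal(tem$max_phase, "Phase 3")
  expect_equal(tem$phase_hist[["Phase 1"]], 10)
  pro <- aggregate_trials("Propofol", registry)
  expect_equal(pro$trial_count, 29)
  expect_equal(pro$max_phase, "Phase 4")
  expect_equal(pro$phase_hist[["Other"]], 19)
  # every histogram axis sums to the trial count
  for (d in unique(registry$drug)) {
    s <- aggregate_trials(d, registry)
    expect_equal(sum(s$phase_hist), s$trial_count)
    expect_equal(sum(s$status_hist), s$trial_count)
    expect_equal(sum(s$cancer_type_hist), s$trial_count)
  }
})

test_that("empty registries and Other-only drugs aggregate sensibly", {
  reg <- expand_phase_counts(data.frame(drug = "lovastatin",
                                        phase = "Other", n_trials = 1))
  none <- aggregate_trials("ghost", reg)
  expect_equal(none$trial_count, 0)
  expect_true(is.na(none$max_phase))
  lone <- aggregate_trials("lovastatin", reg)
  expect_equal(lone$max_phase, "Other")  # Other wins only when alone
  expect_error(expand_phase_counts(data.frame(drug = "x", phase = "Phase 5",
                                              n_trials = 1)), "malformed")
})

test_that("support score counts evidence categories", {
  expect_equal(support_score(TRUE, TRUE, TRUE, TRUE, TRUE), 5L)
  expect_equal(support_score(), 0L)
  expect_equal(support_score(in_vitro = TRUE, in_vivo = TRUE), 2L)
  expect_error(support_score(NA), "defined")
})

test_that("the candidate report assembles rows, flags and summaries", {
  targets <- merge_target_sources(character(0), "ABCB1")
  tab <- data.frame(drug = c("verapamil", "temozolomide", "other"),
                    gene = c("ABCB1", "ABCB1", "ZZZ9"),
                    publication_count = c(2, 5, 1),
                    source_count = c(1, 1, 1))
  rep <- build_candidate_table(targets, tab, licence = "temozolomide")
  expect_equal(nrow(rep$candidates), 2)
  expect_equal(sum(rep$candidates$is_cancer_drug), 1)
  expect_equal(rep$summary$n_targets_with_drug, 1)
  expect_true(rep$targets$has_drug[rep$targets$symbol == "ABCB1"])
  # no drug hits any target
  far <- merge_target_sources(character(0), "NOTHIT")
  rep0 <- build_candidate_table(far, tab)
  expect_equal(nrow(rep0$candidates), 0)
  expect_false(any(rep0$targets$has_drug))
  expect_equal(rep0$summary$pct_targets_with_drug, 0)
})

test_that("an engineered 21-target snapshot reports 13/21 (62%)", {
  targets21 <- read_gene_list(target_panel_file())
  targets <- merge_target_sources(character(0), targets21)
  rep <- build_candidate_table(targets, engineered_interactions())
  expect_equal(rep$summary$n_targets, 21)
  expect_equal(rep$summary$n_targets_with_drug, 13)
  # independent share computation
  expect_equal(rep$summary$pct_targets_with_drug,
               round(100 * 13 / 21))
})

test_that("summary percentages recompute from raw counts", {
  targets <- merge_target_sources(c("A", "B"), c("B", "C", "D"))
  tab <- data.frame(drug = c("d1", "d2"), gene = c("A", "B"),
                    publication_count = 1, source_count = 1)
  rep <- build_candidate_table(targets, tab)
  s <- rep$summary
  expect_equal(s$pct_targets_with_drug,
               round(100 * s$n_targets_with_drug / s$n_targets))
  expect_equal(s$n_drugs, s$n_cancer_drugs + s$n_non_cancer_drugs)
})
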