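# Moderated differential expression, BH adjustment, the significance
# filter, volcano categories and detection-set analysis.

sim_matrix <- function(n_genes, n_per_group, effect = NULL, sd = 0.5,
                       baseline = NULL) {
  baseline <- baseline %||% runif(n_genes, 22, 32)
  genes <- sprintf("G%04d", seq_len(n_genes))
  shift <- setNames(rep(0, n_genes), genes)
  if (!is.null(effect)) shift[names(effect)] <- effect
  x <- cbind(
    matrix(rnorm(n_genes * n_per_group, baseline, sd), n_genes),
    matrix(rnorm(n_genes * n_per_group, baseline + shift, sd), n_genes))
  dimnames(x) <- list(genes, c(paste0("A", seq_len(n_per_group)),
                               paste0("B", seq_len(n_per_group))))
  x
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a gene with identical group values is a perfect null", {
  x <- rbind(G1 = c(1, 1, 1, 1), G2 = c(0, 2, 5, 9))
  colnames(x) <- c("a1", "a2", "b1", "b2")
  res <- moderated_de(x, c("A", "A", "B", "B"))
  g1 <- res[res$gene == "G1", ]
  expect_equal(g1$diff, 0)
  expect_equal(g1$t_mod, 0)
  expect_equal(g1$p, 1)
})

test_that("with prior df forced to zero the moderated t is the pooled t", {
  set.seed(11)
  x <- sim_matrix(60, 3)
  res <- moderated_de(x, rep(c("A", "B"), each = 3), prior_df = 0)
  oracle <- oracle_pooled_t(x, rep(c(TRUE, FALSE), each = 3))
  expect_equal(res$t_mod, unname(oracle[, "t"]), tolerance = 1e-12)
  expect_equal(res$p, unname(oracle[, "p"]), tolerance = 1e-12)
})

test_that("moderated fit agrees with the limma empirical-Bayes pipeline", {
  skip_if_not_installed("limma")
  set.seed(23)
  x <- sim_matrix(200, 2, effect = c(G0001 = 3, G0002 = -3))
  res <- moderated_de(x, rep(c("A", "B"), each = 2))
  design <- cbind(1, rep(c(0, 1), each = 2))
  fit <- limma::eBayes(limma::lmFit(x, design))
  # limma models B - A; ours reports A - B
  expect_equal(res$t_mod, -unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
  expect_equal(attr(res, "prior_df"), fit$df.prior, tolerance = 1e-4)
  # heteroscedastic case: finite prior df
  sds <- exp(rnorm(300, log(0.5), 0.6))
  y <- cbind(matrix(rnorm(300 * 3, 0, sds), 300),
             matrix(rnorm(300 * 3, 0, sds), 300))
  dimnames(y) <- list(sprintf("H%03d", 1:300), paste0("s", 1:6))
  res2 <- moderated_de(y, rep(c("A", "B"), each = 3))
  fit2 <- limma::eBayes(limma::lmFit(y, cbind(1, rep(c(0, 1), each = 3))))
  expect_true(is.finite(attr(res2, "prior_df")))
  expect_equal(attr(res2, "prior_df"), fit2$df.prior, tolerance = 1e-8)
  expect_equal(res2$t_mod, -unname(fit2$t[, 2]), tolerance = 1e-10)
})

test_that("planted effects rank above all null genes", {
  set.seed(5)
  planted <- setNames(rep(3, 10), sprintf("G%04d", 1:10))
  x <- sim_matrix(100, 3, effect = planted, sd = 0.5)
  res <- moderated_de(x, rep(c("A", "B"), each = 3))
  top10 <- res$gene[order(res$p)][1:10]
  expect_setequal(top10, names(planted))
})

test_that("results are invariant to sample and gene reordering", {
  set.seed(31)
  x <- sim_matrix(50, 2)
  g <- rep(c("A", "B"), each = 2)
  base <- moderated_de(x, g)
  perm_s <- c(3, 1, 4, 2)
  res_s <- moderated_de(x[, perm_s], g[perm_s])
  expect_equal(res_s$t_mod, base$t_mod, tolerance = 1e-12)
  perm_g <- sample(nrow(x))
  res_g <- moderated_de(x[perm_g, ], g)
  expect_equal(res_g$t_mod[order(res_g$gene)],
               base$t_mod[order(base$gene)], tolerance = 1e-12)
})

test_that("zero-variance genes are handled through the prior", {
  set.seed(13)
  x <- sim_matrix(40, 2)
  x["G0001", ] <- c(5, 5, 9, 9)  # strong effect, zero residual variance
  res <- moderated_de(x, rep(c("A", "B"), each = 2))
  g1 <- res[res$gene == "G0001", ]
  expect_true(is.finite(g1$t_mod))
  expect_lt(g1$p, 0.01)
})

test_that("a group with zero samples is rejected", {
  x <- sim_matrix(10, 2)
  expect_error(moderated_de(x, rep("A", 4)), "two groups")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(99)
  for (i in 1:5) {
    p <- runif(5)
    perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 5), ]
    for (r in seq_len(nrow(perms))) {
      pp <- p[perms[r, ]]
      expect_equal(bh_adjust(pp), oracle_bh(pp), tolerance = 1e-14)
    }
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Q values never fall below their p-values", {
  set.seed(8)
  p <- runif(200)^2
  expect_true(all(bh_adjust(p) >= p))
})

test_that("the significance filter applies the Q, delta-Ct and Ct rules", {
  res <- data.frame(gene = c("A", "B", "C"),
                    mean_dct_a = 0, mean_dct_b = 0,
                    diff = c(2.5, 1.5, 3.5), t_mod = 1,
                    p = 0.01, q = c(0.05, 0.05, 0.05),
                    excluded = FALSE, significant = FALSE)
  cts <- data.frame(gene = c("A", "B", "C"),
                    ct_a = c(28, 28, 36), ct_b = c(29, 29, 37))
  out <- apply_significance_filter(res, cts)
  expect_true(out$significant[out$gene == "A"])
  expect_false(out$significant[out$gene == "B"])   # |diff| <= 2
  expect_true(out$excluded[out$gene == "C"])       # Ct > 35 in both
  expect_false(out$significant[out$gene == "C"])
  # reference-only exclusion variant
  cts2 <- data.frame(gene = c("A", "B", "C"),
                     ct_a = c(36, 28, 36), ct_b = c(20, 29, 20))
  ref <- apply_significance_filter(res, cts2, exclude_mode = "reference")
  expect_true(ref$excluded[ref$gene == "A"])
  both <- apply_significance_filter(res, cts2, exclude_mode = "both")
  expect_false(both$excluded[both$gene == "A"])
})

test_that("volcano categories follow sign and thresholds", {
  res <- data.frame(gene = c("up", "down", "flat"),
                    diff = c(3, -3, 0.5), q = c(0.01, 0.01, 0.5))
  v <- volcano_table(res)
  expect_equal(v$category, c("increased_3d", "decreased_3d", "ns"))
})

test_that("detection-set analysis matches hand enumeration", {
  genes <- sprintf("g%02d", 1:10)
  ta <- setNames(c("HIGH", "HIGH", "EXPRESSED", "EXPRESSED", "EXPRESSED",
                   "NOT_DETECTED", "NOT_DETECTED", "HIGH", "EXPRESSED",
                   "NOT_DETECTED"), genes)
  tb <- setNames(c("HIGH", "EXPRESSED", "EXPRESSED", "NOT_DETECTED",
                   "EXPRESSED", "NOT_DETECTED", "EXPRESSED", "HIGH",
                   "HIGH", "NOT_DETECTED"), genes)
  d <- detection_set_analysis(ta, tb)
  # hand count: detected in both = g01,g02,g03,g05,g08,g09 (6)
  expect_equal(d$shared_detected, 6)
  expect_equal(d$shared_high, 2)              # g01, g08
  expect_equal(d$not_detected_both, 2)        # g06, g10
  expect_equal(d$unique_undetected_a, 1)      # g07
  expect_equal(d$unique_undetected_b, 1)      # g04
  expect_equal(d$panel_size, 10)
  expect_equal(unname(d$percentages["shared_detected"]), 60)
  expect_equal(unname(d$percentages["shared_high_of_detected"]),
               round(100 * 2 / 6))
})

test_that("detection-set extremes and symmetry behave", {
  genes <- letters[1:6]
  all_det <- setNames(rep("EXPRESSED", 6), genes)
  none <- setNames(rep("NOT_DETECTED", 6), genes)
  d <- detection_set_analysis(all_det, none)
  expect_equal(d$shared_detected, 0)
  expect_equal(d$unique_undetected_b, 6)
  same <- detection_set_analysis(all_det, all_det)
  expect_equal(same$unique_undetected_a, 0)
  expect_equal(same$unique_undetected_b, 0)
  expect_error(detection_set_analysis(all_det, none[1:5]), "same gene panel")
})
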