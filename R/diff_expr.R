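# Moderated two-group differential expression on delta-Ct values,
# Benjamini-Hochberg Q values, the Ct-based significance filter, volcano
# categorisation and detection-set (Venn) analysis.

#' Empirical-Bayes moderated two-group differential expression
#'
#' Fits an ordinary two-group linear model per gene on delta-Ct values and
#' moderates the residual variances by shrinking them toward a common
#' prior estimated by method of moments on the log residual variances
#' (prior degrees of freedom from a trigamma inversion). The moderated
#' statistic is `t = diff / (s_post * sqrt(1/nA + 1/nB))` with
#' `df = residual df + prior df`; with only two replicates per group the
#' shrinkage carries most of the degrees of freedom.
#'
#' The group listed first in `levels` (or `"2D"` when present) is group A,
#' and `diff = mean(A) - mean(B)`; on the Ct scale a positive `diff` means
#' the gene is more highly expressed in group B.
#'
#' @param dct Numeric genes x samples matrix of delta-Ct values with row
#'   and column names.
#' @param groups Character/factor of group labels, either named by sample
#'   or aligned with `colnames(dct)`; exactly two groups, each non-empty.
#' @param prior_df Override for the prior degrees of freedom: `NULL`
#'   (default) estimates it; `0` disables shrinkage, recovering the
#'   ordinary pooled two-sample t-test; `Inf` fully pools variances.
#' @return Data frame of class `de_result` with columns `gene`,
#'   `mean_dct_a`, `mean_dct_b`, `diff`, `t_mod`, `p`, `q`, `excluded`,
#'   `significant`, plus attributes `prior_df`, `prior_var`,
#'   `residual_df` and `groups`.
#' @export
moderated_de <- function(dct, groups, prior_df = NULL) {
  stopifnot(is.matrix(dct), is.numeric(dct), nrow(dct) >= 2)
  if (is.null(rownames(dct))) stop("dct must have gene rownames")
  groups <- as_group_factor(groups, colnames(dct), ncol(dct))
  a <- levels(groups)[1]; b <- levels(groups)[2]
  na <- sum(groups == a); nb <- sum(groups == b)
  if (na == 0 || nb == 0) stop("each group needs at least one sample")
  d <- na + nb - 2L
  if (d < 1)
    stop("need at least three samples overall for a residual variance")
  xa <- dct[, groups == a, drop = FALSE]
  xb <- dct[, groups == b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ss <- rowSums((xa - ma)^2) + rowSums((xb - mb)^2)
  s2 <- ss / d
  eb <- if (is.null(prior_df)) moments_prior(s2, d)
        else list(df = prior_df, var = if (is.finite(prior_df) && prior_df > 0)
          moments_prior(s2, d)$var else mean(s2))
  d0 <- eb$df; s02 <- eb$var
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  diff <- ma - mb
  t_mod <- ifelse(diff == 0, 0, diff / se)
  # total df capped at the pooled residual df across the panel
  df_tot <- min(d + d0, d * nrow(dct))
  p <- 2 * pt(-abs(t_mod), df = df_tot)
  p[diff == 0] <- 1
  res <- data.frame(gene = rownames(dct),
                    mean_dct_a = unname(ma), mean_dct_b = unname(mb),
                    diff = unname(diff), t_mod = unname(t_mod),
                    p = unname(p), q = bh_adjust(unname(p)),
                    excluded = FALSE, significant = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "prior_df") <- d0
  attr(res, "prior_var") <- s02
  attr(res, "residual_df") <- d
  attr(res, "groups") <- c(a = a, b = b)
  class(res) <- c("de_result", "data.frame")
  res
}

as_group_factor <- function(groups, sample_names, n) {
  g <- if (is.factor(groups)) as.character(groups) else as.character(groups)
  if (!is.null(names(groups)) && !is.null(sample_names)) {
    missing <- setdiff(sample_names, names(groups))
    if (length(missing))
      stop("no group assignment for samples: ", paste(missing, collapse = ", "))
    g <- g[match(sample_names, names(groups))]
  }
  if (length(g) != n) stop("groups must cover every sample column")
  lev <- if (is.factor(groups)) levels(groups) else sort(unique(g))
  if ("2D" %in% lev) lev <- c("2D", setdiff(lev, "2D"))
  if (length(lev) != 2) stop("exactly two groups are required, got: ",
                             paste(lev, collapse = ", "))
  factor(g, levels = lev)
}

# Method-of-moments estimate of the scaled inverse-chi-square prior on
# residual variances, on the log scale (Fisher's z for log variances):
# E[log s2] = log s02 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
# Var[log s2] = trigamma(d/2) + trigamma(d0/2).
moments_prior <- function(s2, d) {
  z <- log(s2)
  ok <- is.finite(z)
  if (!any(ok))
    stop("no gene carries residual variance information")
  e <- z[ok] - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- if (sum(ok) > 1) var(e) else 0
  evar <- evar - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond sampling noise: variances fully pooled
    d0 <- Inf
    s02 <- mean(s2)
  }
  list(df = d0, var = s02)
}

# Solve trigamma(x) = y by Newton iteration on the monotone decreasing
# trigamma function (convex in 1/x, so iterate on x directly).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg adjusted Q values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' output order matches input order.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Numeric vector of Q values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    stop("p-values must be finite and in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Apply the Ct-based significance filter
#'
#' A gene is flagged significant when its Q value is below `q_cut`, the
#' absolute group-mean delta-Ct difference exceeds `dct_cut` cycles, and
#' the gene is not excluded by the Ct detection rule. The default
#' exclusion rule (`exclude_mode = "both"`) removes genes whose mean Ct
#' exceeds `ct_detect` in both populations; `"reference"` removes genes
#' undetected in the reference (group A / 2D) population only.
#'
#' @param results A `de_result` data frame from [moderated_de()].
#' @param ct_group_means Data frame with columns `gene`, `ct_a`, `ct_b`:
#'   per-gene mean raw Ct in each group (see [group_mean_ct()]).
#' @param q_cut,dct_cut,ct_detect Thresholds (defaults 0.1, 2, 35).
#' @param exclude_mode `"both"` or `"reference"`.
#' @return The results with `excluded` and `significant` filled in.
#' @export
apply_significance_filter <- function(results, ct_group_means,
                                      q_cut = 0.1, dct_cut = 2,
                                      ct_detect = CT_DETECT,
                                      exclude_mode = c("both", "reference")) {
  exclude_mode <- match.arg(exclude_mode)
  stopifnot(all(c("gene", "ct_a", "ct_b") %in% names(ct_group_means)))
  idx <- match(results$gene, ct_group_means$gene)
  if (anyNA(idx))
    stop("Ct table does not cover genes: ",
         paste(results$gene[is.na(idx)], collapse = ", "))
  ct_a <- ct_group_means$ct_a[idx]
  ct_b <- ct_group_means$ct_b[idx]
  results$excluded <- if (exclude_mode == "both")
    ct_a > ct_detect & ct_b > ct_detect else ct_a > ct_detect
  results$significant <- results$q < q_cut &
    abs(results$diff) > dct_cut & !results$excluded
  results
}

#' Per-gene mean raw Ct by group
#'
#' @param dctm A `dct_matrix` object from [build_dct_matrix()].
#' @param groups Optional group labels (defaults to the samples'
#'   conditions).
#' @return Data frame `gene`, `ct_a`, `ct_b`.
#' @export
group_mean_ct <- function(dctm, groups = NULL) {
  stopifnot(inherits(dctm, "dct_matrix"))
  groups <- as_group_factor(groups %||%
      setNames(dctm$samples$condition, dctm$samples$sample_id),
    colnames(dctm$ct), ncol(dctm$ct))
  a <- levels(groups)[1]; b <- levels(groups)[2]
  data.frame(gene = rownames(dctm$ct),
             ct_a = rowMeans(dctm$ct[, groups == a, drop = FALSE]),
             ct_b = rowMeans(dctm$ct[, groups == b, drop = FALSE]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Volcano-plot table
#'
#' Categorises every gene by the sign of its delta-Ct difference and the
#' significance thresholds: `increased_3d` for `diff > dct_cut` and
#' `q < q_cut` (lower Ct in 3D, i.e. more RNA), `decreased_3d` for the
#' mirror case, `ns` otherwise.
#'
#' @param results A `de_result` data frame.
#' @param q_cut,dct_cut Thresholds (defaults 0.1, 2).
#' @return Data frame `gene`, `diff`, `q`, `category`.
#' @export
volcano_table <- function(results, q_cut = 0.1, dct_cut = 2) {
  if (!nrow(results)) stop("no differential expression results")
  sig <- results$q < q_cut & abs(results$diff) > dct_cut
  category <- ifelse(sig & results$diff > 0, "increased_3d",
                     ifelse(sig & results$diff < 0, "decreased_3d", "ns"))
  data.frame(gene = results$gene, diff = results$diff, q = results$q,
             category = category, stringsAsFactors = FALSE, row.names = NULL)
}

#' Detection-set (Venn) analysis of two tier maps
#'
#' Compares the expression tiers of a shared gene panel between two
#' populations and counts genes not detected in both, uniquely undetected
#' in each, detected in both, and - of the shared-detected set - highly
#' expressed in both. Percentages are integer-rounded (half away from
#' zero) over the panel size; `shared_high_of_detected` is additionally
#' reported relative to the shared-detected count.
#'
#' @param tiers_a,tiers_b Named factors/characters of tiers (values in
#'   `HIGH`, `EXPRESSED`, `NOT_DETECTED`) over the same gene panel.
#' @return Object of class `detection_summary`: list of counts,
#'   `panel_size` and a `percentages` named vector.
#' @export
detection_set_analysis <- function(tiers_a, tiers_b) {
  na <- names(tiers_a); nb <- names(tiers_b)
  if (is.null(na) || is.null(nb) || !setequal(na, nb))
    stop("tier maps must be named over the same gene panel")
  ta <- as.character(tiers_a)[match(na, na)]
  tb <- as.character(tiers_b)[match(na, nb)]
  stopifnot(all(ta %in% TIER_LEVELS), all(tb %in% TIER_LEVELS))
  det_a <- ta != "NOT_DETECTED"; det_b <- tb != "NOT_DETECTED"
  counts <- c(
    shared_detected = sum(det_a & det_b),
    shared_high = sum(ta == "HIGH" & tb == "HIGH"),
    not_detected_both = sum(!det_a & !det_b),
    unique_undetected_a = sum(!det_a & det_b),
    unique_undetected_b = sum(det_a & !det_b))
  n <- length(ta)
  pct <- round_half_up(100 * counts / n)
  pct["shared_high_of_detected"] <- if (counts[["shared_detected"]] > 0)
    round_half_up(100 * counts[["shared_high"]] / counts[["shared_detected"]])
    else 0
  structure(c(as.list(counts), list(panel_size = n, percentages = pct)),
            class = "detection_summary")
}

#' @export
print.detection_summary <- function(x, ...) {
  cat(sprintf(
    "<detection_summary> panel %d: detected in both %d (%d%%), high in both %d, not detected in both %d (%d%%), unique undetected %d/%d\n",
    x$panel_size, x$shared_detected, x$percentages[["shared_detected"]],
    x$shared_high, x$not_detected_both,
    x$percentages[["not_detected_both"]],
    x$unique_undetected_a, x$unique_undetected_b))
  invisible(x)
}
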