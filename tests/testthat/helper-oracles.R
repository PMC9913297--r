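# Independent oracles used across the suite. Each is a deliberately
# naive, literal implementation kept separate from the package code paths
# it is used to check.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m p_(j) / j,
# computed by explicit loops on the sorted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Ordinary pooled two-sample t-test per row (textbook formula).
oracle_pooled_t <- function(x, ga) {
  xa <- x[, ga, drop = FALSE]
  xb <- x[, !ga, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  t(apply(x, 1, function(r) {
    a <- r[ga]; b <- r[!ga]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
    tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    c(t = tt, p = 2 * pt(-abs(tt), df = na + nb - 2))
  }))
}

# Literal evaluation of the interaction-score formula for one edge,
# recounting every partner set from scratch.
oracle_interaction_score <- function(drug, gene, tab) {
  pub <- tab$publication_count[tab$drug == drug & tab$gene == gene]
  src <- tab$source_count[tab$drug == drug & tab$gene == gene]
  genes_of <- function(d) unique(tab$gene[tab$drug == d])
  drugs_of <- function(g) unique(tab$drug[tab$gene == g])
  all_drugs <- unique(tab$drug)
  all_genes <- unique(tab$gene)
  avg_gpd <- mean(vapply(all_drugs, function(d) length(genes_of(d)), 0))
  avg_dpg <- mean(vapply(all_genes, function(g) length(drugs_of(g)), 0))
  (pub + src) * (avg_gpd / length(genes_of(drug))) *
    (avg_dpg / length(drugs_of(gene)))
}

# Exhaustive maximal-clique enumeration over all vertex subsets (n <= 12).
oracle_max_cliques <- function(edges, universe, k) {
  universe <- sort(toupper(universe))
  n <- length(universe)
  adj <- matrix(FALSE, n, n, dimnames = list(universe, universe))
  for (i in seq_len(nrow(edges))) {
    a <- toupper(edges$a[i]); b <- toupper(edges$b[i])
    if (a %in% universe && b %in% universe) {
      adj[a, b] <- TRUE; adj[b, a] <- TRUE
    }
  }
  is_clique <- function(v) all(adj[v, v][upper.tri(diag(length(v)))])
  subsets <- lapply(seq_len(2^n) - 1, function(m)
    universe[bitwAnd(m, 2^(seq_len(n) - 1)) > 0])
  cliques <- Filter(function(v) length(v) >= k && is_clique(v), subsets)
  maximal <- Filter(function(v) {
    !any(vapply(setdiff(universe, v), function(u)
      is_clique(c(v, u)), TRUE))
  }, cliques)
  maximal <- lapply(maximal, sort)
  key <- vapply(maximal, paste, "", collapse = "|")
  maximal[order(-lengths(maximal), key)]
}

# Random small drug-gene table with every drug and gene used at least once.
random_interaction_table <- function(n_drugs, n_genes) {
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  genes <- sprintf("g%02d", seq_len(n_genes))
  grid <- expand.grid(drug = drugs, gene = toupper(genes),
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < runif(1, 0.15, 0.6)
  tab <- grid[keep, , drop = FALSE]
  lonely <- setdiff(drugs, tab$drug)
  if (length(lonely))
    tab <- rbind(tab, data.frame(drug = lonely,
                                 gene = sample(toupper(genes),
                                               length(lonely), TRUE),
                                 stringsAsFactors = FALSE))
  tab <- tab[!duplicated(paste(tab$drug, tab$gene)), ]
  tab$publication_count <- sample(0:20, nrow(tab), replace = TRUE)
  tab$source_count <- sample(0:6, nrow(tab), replace = TRUE)
  rownames(tab) <- NULL
  tab
}

# A tiny in-memory card for normalisation tests.
toy_card <- function(ct, genes = sprintf("T%02d", seq_along(ct)),
                     sample_id = "S1", condition = "2D",
                     platform = "PLURIPOTENCY") {
  ct_card(sample_id, condition, platform,
          data.frame(gene = genes, ct = ct, detected = ct <= 35,
                     is_control = FALSE, stringsAsFactors = FALSE))
}
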