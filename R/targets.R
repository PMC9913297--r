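# Target prioritisation: merging differential-expression hits with the
# patient-derived ES-CSC gene list (source codes 1/2), plus interaction
# structure of the target set from a protein-association edge list.

EVIDENCE_CHANNELS <- c("experimental", "curated", "coexpression", "textmining")

#' Merge differential-expression and ES-CSC target sources
#'
#' Builds the prioritised target set as the case-insensitive union of the
#' genes increased in 3D spheroids (source code 2) and the patient-derived
#' ES-CSC gene list (source code 1). Genes present in both carry `"1,2"`.
#'
#' @param de_up Character vector of genes increased in the 3D/CSC group.
#' @param escsc_list Character vector of patient-derived ES-CSC genes.
#' @return Data frame of class `target_set`: `symbol` (upper-case, sorted),
#'   `sources` (`"1"`, `"2"` or `"1,2"`), `has_drug` (NA until the
#'   repurposing stage fills it).
#' @export
merge_target_sources <- function(de_up, escsc_list) {
  de_up <- unique(toupper(trimws(de_up[nzchar(de_up)])))
  escsc <- unique(toupper(trimws(escsc_list[nzchar(escsc_list)])))
  if (!length(de_up) && !length(escsc))
    stop("both target source lists are empty")
  symbols <- sort(union(de_up, escsc))
  sources <- vapply(symbols, function(s) {
    paste(c("1"[s %in% escsc], "2"[s %in% de_up]), collapse = ",")
  }, "")
  structure(data.frame(symbol = symbols, sources = unname(sources),
                       has_drug = NA, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("target_set", "data.frame"))
}

#' Read a one-symbol-per-line gene list
#'
#' Blank lines and lines starting with `#` are ignored; symbols are
#' upper-cased.
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  toupper(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read a protein-association edge list
#'
#' Expects TSV columns `a`, `b`, `evidence` with evidence in
#' `experimental`, `curated`, `coexpression`, `textmining`. Edges are
#' undirected; self-loops are rejected and duplicate/reversed edges are
#' collapsed.
#'
#' @param path Path to the edge-list TSV.
#' @return Data frame `a`, `b`, `evidence`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  e <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("a", "b", "evidence"), names(e))
  if (length(missing))
    stop("edge list missing columns: ", paste(missing, collapse = ", "))
  e$a <- toupper(trimws(e$a)); e$b <- toupper(trimws(e$b))
  e$evidence <- tolower(trimws(e$evidence))
  bad <- !e$evidence %in% EVIDENCE_CHANNELS
  if (any(bad))
    stop("unknown evidence channel: ", paste(unique(e$evidence[bad]),
                                             collapse = ", "))
  if (any(e$a == e$b))
    stop("self-loop edges are not allowed: ",
         paste(unique(e$a[e$a == e$b]), collapse = ", "))
  key <- paste(pmin(e$a, e$b), pmax(e$a, e$b), e$evidence)
  e[!duplicated(key), c("a", "b", "evidence"), drop = FALSE]
}

filter_edges <- function(edges, universe = NULL, evidence = NULL) {
  if (!is.null(evidence)) edges <- edges[edges$evidence %in% evidence, ]
  if (!is.null(universe)) {
    universe <- toupper(universe)
    edges <- edges[edges$a %in% universe & edges$b %in% universe, ]
  }
  edges
}

#' Degree of a target gene within the target universe
#'
#' Number of distinct neighbours of `node` among the universe genes
#' (undirected, duplicates and reversed edges counted once, the node
#' itself excluded).
#'
#' @param edges Edge-list data frame (`a`, `b`, `evidence`).
#' @param node Gene symbol; must belong to the universe.
#' @param universe Character vector of target genes.
#' @param evidence Optional subset of evidence channels to count; all
#'   channels by default.
#' @return Integer neighbour count.
#' @export
target_degree <- function(edges, node, universe, evidence = NULL) {
  node <- toupper(node); universe <- toupper(universe)
  if (!length(universe)) stop("universe must be non-empty")
  if (!node %in% universe) stop("node ", node, " is not in the universe")
  e <- filter_edges(edges, universe, evidence)
  nb <- union(e$b[e$a == node], e$a[e$b == node])
  length(setdiff(nb, node))
}

#' Maximal mutually-interacting cores (cliques) of the target set
#'
#' Finds all maximal sets of at least `k` target genes whose induced
#' subgraph is complete, i.e. groups of gene products that all pairwise
#' interact. Results are ordered by decreasing size, then lexicographically.
#'
#' @param edges Edge-list data frame.
#' @param universe Target gene set defining the induced subgraph.
#' @param k Minimum clique size (>= 2).
#' @param evidence Optional evidence-channel filter.
#' @return List of character vectors (each sorted), possibly empty.
#' @export
mutually_interacting_core <- function(edges, universe, k = 2,
                                      evidence = NULL) {
  stopifnot(k >= 2)
  universe <- toupper(universe)
  e <- filter_edges(edges, universe, evidence)
  if (!nrow(e)) return(list())
  g <- igraph::simplify(igraph::graph_from_data_frame(
    e[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = universe)))
  cl <- igraph::max_cliques(g, min = k)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  key <- vapply(cl, paste, "", collapse = "|")
  cl[order(-lengths(cl), key)]
}

#' Connected cores of the target set
#'
#' Companion statistic to [mutually_interacting_core()]: connected
#' components of the induced subgraph with at least `k` members (genes
#' linked directly or indirectly, not necessarily pairwise-complete).
#'
#' @inheritParams mutually_interacting_core
#' @return List of sorted character vectors.
#' @export
connected_cores <- function(edges, universe, k = 2, evidence = NULL) {
  stopifnot(k >= 2)
  universe <- toupper(universe)
  e <- filter_edges(edges, universe, evidence)
  if (!nrow(e)) return(list())
  g <- igraph::simplify(igraph::graph_from_data_frame(
    e[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = universe)))
  comp <- igraph::components(g)
  out <- split(igraph::V(g)$name, comp$membership)
  out <- lapply(unname(out), sort)
  out <- out[lengths(out) >= k]
  key <- vapply(out, paste, "", collapse = "|")
  out[order(-lengths(out), key)]
}
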