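#' Build a thresholded co-expression network
#'
#' Undirected network over a gene set with an edge wherever the Pearson
#' correlation of expression across samples strictly exceeds `r_threshold`.
#' Constant genes are excluded (correlation undefined) and unconnected genes
#' removed.
#'
#' @param values Gene-by-sample expression matrix for the gene set.
#' @param r_threshold Correlation threshold (edges require `r > threshold`).
#' @param ev Optional named vector of variability scores stored as a node
#'   attribute (node sizing).
#' @return An `igraph` graph with edge attribute `r` and node attribute
#'   `ev` (if supplied).
#' @export
build_network <- function(values, r_threshold = 0.6, ev = NULL) {
  values <- unclass(values)
  if (nrow(values) < 3) stop("need at least 3 genes")
  if (ncol(values) < 8) stop("need at least 8 samples")
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding %d constant genes (undefined correlation)",
                    sum(sds == 0)))
    values <- values[sds > 0, , drop = FALSE]
  }
  cc <- stats::cor(t(values))
  adj <- cc > r_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  r_vals <- cc[igraph::as_edgelist(g, names = FALSE)]
  igraph::E(g)$r <- r_vals
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (!is.null(ev))
    igraph::V(g)$ev <- unname(ev[igraph::V(g)$name])
  g
}

# edge clustering coefficient: (triangles + 1) / min(deg_u - 1, deg_v - 1),
# or triangles + 1 when either endpoint has degree <= 1
edge_ecc <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  adj <- igraph::as_adj_list(g)
  tri <- vapply(seq_len(nrow(el)), function(i) {
    length(intersect(adj[[el[i, 1]]], adj[[el[i, 2]]]))
  }, numeric(1))
  denom <- pmin(deg[el[, 1]], deg[el[, 2]]) - 1
  ifelse(denom <= 0, tri + 1, (tri + 1) / denom)
}

#' Detect network modules by edge-clustering-coefficient agglomeration
#'
#' FAG-EC-style agglomerative clustering: edges are processed in descending
#' edge clustering coefficient (ECC, a triangle-density score; ties broken
#' by edge id), merging the clusters of their endpoints; a merge is refused
#' once both clusters have already reached `min_size`, which keeps mature
#' modules separate across low-ECC bridge edges. Clusters smaller than
#' `min_size` are discarded. Deterministic for a given graph.
#'
#' @param g An `igraph` network from [build_network()].
#' @param min_size Minimum module size.
#' @param method `"ecc"` for the ECC agglomeration (default) or
#'   `"components"` for plain connected components of at least `min_size`.
#' @return List of character vectors (module node sets), largest first.
#' @export
detect_modules <- function(g, min_size = 5, method = c("ecc", "components")) {
  method <- match.arg(method)
  n <- igraph::vcount(g)
  if (n == 0) return(list())
  if (method == "components") {
    comp <- igraph::components(g)
    groups <- split(igraph::V(g)$name, comp$membership)
    groups <- Filter(function(x) length(x) >= min_size, groups)
    groups <- unname(groups[order(-vapply(groups, length, integer(1)),
                                  vapply(groups, min, character(1)))])
    return(lapply(groups, sort))
  }
  el_names <- igraph::as_edgelist(g)
  edge_id <- paste(pmin(el_names[, 1], el_names[, 2]),
                   pmax(el_names[, 1], el_names[, 2]), sep = "|")
  ecc <- edge_ecc(g)
  ord <- order(-ecc, edge_id)
  el <- igraph::as_edgelist(g, names = FALSE)[ord, , drop = FALSE]
  storage.mode(el) <- "integer"
  parent <- seq_len(n)
  csize <- rep(1L, n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(el))) {
    ru <- find(el[e, 1]); rv <- find(el[e, 2])
    if (ru == rv) next
    if (csize[ru] >= min_size && csize[rv] >= min_size) next
    parent[rv] <- ru
    csize[ru] <- csize[ru] + csize[rv]
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(igraph::V(g)$name, root)
  groups <- Filter(function(x) length(x) >= min_size, groups)
  groups <- unname(groups[order(-vapply(groups, length, integer(1)),
                                vapply(groups, min, character(1)))])
  lapply(groups, sort)
}

#' Write a network as an edge-list TSV and GraphML
#'
#' @param g An `igraph` graph.
#' @param edge_path Path of the edge-list TSV (`from`, `to`, `r`).
#' @param graphml_path Optional path for a GraphML export.
#' @return Invisibly, the edge-list data frame.
#' @export
write_network <- function(g, edge_path, graphml_path = NULL) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(from = el[, 1], to = el[, 2], r = igraph::E(g)$r,
                   row.names = NULL)
  utils::write.table(df, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(df)
}
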