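#' Construct an attributed graph
#'
#' The central container of the package: a simple undirected graph with
#' optional node features, node/graph labels, and a symmetric sparse
#' adjacency matrix. Nodes are identified internally by the contiguous
#' integers `1..n_nodes`; the original external identifiers (from an edge
#' list or GraphML file) are kept in `node_names`.
#'
#' Input graphs are simple: parallel edges are collapsed into one edge with
#' summed weight, and self-loops are dropped with a warning. Self-loops only
#' appear later, when pooling adds the identity term to the adjacency.
#'
#' @param edges two-column integer matrix of endpoints in `1..n_nodes`
#'   (one row per undirected edge; orientation irrelevant), or `NULL` /
#'   zero-row matrix for an edgeless graph.
#' @param n_nodes number of nodes (allows isolated nodes beyond the edge list).
#' @param features optional numeric matrix with one row per node.
#' @param labels optional integer vector of per-node class labels.
#' @param weights optional positive edge weights (recycled to one per edge);
#'   defaults to 1.
#' @param node_names original external node identifiers (character); defaults
#'   to `as.character(seq_len(n_nodes) - 1)`.
#' @param name free-text graph name.
#'
#' @return An object of class `attributed_graph`: a list with elements
#'   `n_nodes`, `edges` (canonical two-column matrix, `u <= v`, ordered),
#'   `weights`, `adjacency` (symmetric `dgCMatrix`, zero diagonal),
#'   `features`, `labels`, `node_names`, `name`.
#' @export
attributed_graph <- function(edges = NULL, n_nodes, features = NULL,
                             labels = NULL, weights = NULL,
                             node_names = NULL, name = "") {
  n_nodes <- as.integer(n_nodes)
  if (is.na(n_nodes) || n_nodes < 0) stop("n_nodes must be a nonnegative integer")
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(integer(0), ncol = 2)
    weights <- numeric(0)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2)
    if (anyNA(edges)) stop("edge endpoints must be integers")
    if (any(edges < 1L) || any(edges > n_nodes)) {
      stop("edge endpoint out of range 1..", n_nodes)
    }
    if (is.null(weights)) weights <- rep(1, nrow(edges))
    weights <- rep_len(as.numeric(weights), nrow(edges))
    loops <- edges[, 1] == edges[, 2]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped from input graph")
      edges <- edges[!loops, , drop = FALSE]
      weights <- weights[!loops]
    }
    # canonical orientation u <= v, collapse parallel edges with summed weight
    u <- pmin(edges[, 1], edges[, 2])
    v <- pmax(edges[, 1], edges[, 2])
    key <- paste(u, v)
    if (anyDuplicated(key)) {
      agg <- rowsum(weights, key, reorder = FALSE)
      keep <- !duplicated(key)
      u <- u[keep]; v <- v[keep]
      weights <- as.numeric(agg[match(unique(key), rownames(agg))])
    }
    ord <- order(u, v)
    edges <- cbind(u = u[ord], v = v[ord])
    weights <- weights[ord]
  }
  if (!is.null(features)) {
    features <- as.matrix(features)
    storage.mode(features) <- "double"
    if (nrow(features) != n_nodes) {
      stop("feature row count (", nrow(features), ") must equal node count (",
           n_nodes, ")")
    }
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n_nodes) stop("labels length must equal node count")
  }
  if (is.null(node_names)) node_names <- as.character(seq_len(n_nodes) - 1L)
  adjacency <- edges_to_adjacency(edges, weights, n_nodes)
  structure(
    list(n_nodes = n_nodes, edges = edges, weights = weights,
         adjacency = adjacency, features = features, labels = labels,
         node_names = as.character(node_names), name = name),
    class = "attributed_graph"
  )
}

edges_to_adjacency <- function(edges, weights, n_nodes) {
  if (nrow(edges) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n_nodes, n_nodes)))
  }
  Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]), j = c(edges[, 2], edges[, 1]),
    x = c(weights, weights), dims = c(n_nodes, n_nodes)
  )
}

#' @export
print.attributed_graph <- function(x, ...) {
  cat(sprintf("attributed_graph '%s': %d nodes, %d edges", x$name, x$n_nodes,
              nrow(x$edges)))
  if (!is.null(x$features)) cat(sprintf(", %d features", ncol(x$features)))
  if (!is.null(x$labels)) cat(sprintf(", %d classes", length(unique(x$labels))))
  cat("\n")
  invisible(x)
}

#' Number of edges of an attributed graph
#' @param g an `attributed_graph`.
#' @return integer edge count.
#' @export
n_edges <- function(g) nrow(g$edges)

#' Convert an attributed graph to an igraph object
#'
#' @param g an `attributed_graph`.
#' @return an undirected `igraph` graph with `name` vertex attribute carrying
#'   the external ids and `weight` edge attribute.
#' @export
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = g$n_nodes, directed = FALSE)
  if (nrow(g$edges) > 0) {
    ig <- igraph::add_edges(ig, as.integer(t(g$edges)))
    igraph::E(ig)$weight <- g$weights
  }
  igraph::V(ig)$name <- g$node_names
  ig
}

#' Node degrees (weighted or unweighted)
#' @param g an `attributed_graph`.
#' @param weighted if `TRUE`, sum edge weights instead of counting edges.
#' @return numeric vector of length `n_nodes`.
#' @export
node_degrees <- function(g, weighted = FALSE) {
  if (weighted) as.numeric(Matrix::rowSums(g$adjacency))
  else as.numeric(Matrix::rowSums(g$adjacency != 0))
}

#' Construct a graph-classification dataset
#'
#' An ordered collection of attributed graphs with one class label per graph.
#'
#' @param graphs list of `attributed_graph` objects.
#' @param graph_labels integer class per graph; class ids must be dense from 0.
#' @param split_seed integer seed governing any subsequent train/validation
#'   split.
#' @return an object of class `graph_dataset`.
#' @export
graph_dataset <- function(graphs, graph_labels, split_seed = 0L) {
  stopifnot(is.list(graphs), all(vapply(graphs, inherits, TRUE, "attributed_graph")))
  graph_labels <- as.integer(graph_labels)
  if (length(graph_labels) != length(graphs)) {
    stop("graph_labels length must equal number of graphs")
  }
  classes <- sort(unique(graph_labels))
  if (!identical(classes, seq_along(classes) - 1L)) {
    stop("class ids must be dense integers starting at 0")
  }
  structure(list(graphs = graphs, graph_labels = graph_labels,
                 split_seed = as.integer(split_seed)),
            class = "graph_dataset")
}

#' @export
print.graph_dataset <- function(x, ...) {
  cat(sprintf("graph_dataset: %d graphs, %d classes\n", length(x$graphs),
              length(unique(x$graph_labels))))
  invisible(x)
}
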