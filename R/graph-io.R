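#' Read a graph from disk
#'
#' Reads an edge list (whitespace/TSV `u v [weight]`) or a GraphML file into
#' an [attributed_graph()]. External node ids are remapped to the contiguous
#' internal ids `1..N`; the original ids are preserved in `node_names` so the
#' mapping is recoverable. Directed GraphML input is symmetrized with a
#' warning. A node-feature table (CSV/TSV with header `node_id,f1,...,fk`,
#' one row per node keyed by the external id) may be attached.
#'
#' @param path input file.
#' @param format `"edgelist"` or `"graphml"`.
#' @param features_path optional CSV/TSV feature table.
#' @return an `attributed_graph`.
#' @export
read_graph <- function(path, format = c("edgelist", "graphml"),
                       features_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  g <- switch(format,
    edgelist = read_edgelist(path),
    graphml = read_graphml(path)
  )
  if (!is.null(features_path)) {
    g <- attach_features(g, features_path)
  }
  g
}

read_edgelist <- function(path) {
  lines <- readLines(path)
  keep <- grepl("\\S", lines) & !grepl("^\\s*#", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  n_tok <- lengths(toks)
  bad <- which(n_tok < 2 | n_tok > 3)
  if (length(bad) > 0) {
    stop("edge list format error at line ", idx[bad[1]], ": '",
         lines[idx[bad[1]]], "' (expected 'u v [weight]')")
  }
  u <- vapply(toks, `[`, "", 1L)
  v <- vapply(toks, `[`, "", 2L)
  w <- vapply(toks, function(t) {
    if (length(t) == 3) suppressWarnings(as.numeric(t[3])) else 1
  }, 0)
  if (anyNA(w)) {
    bad <- which(is.na(w))[1]
    stop("edge list format error at line ", idx[bad],
         ": non-numeric weight '", toks[[bad]][3], "'")
  }
  ids <- unique(c(u, v))
  # numeric external ids sort numerically, otherwise lexicographically
  num <- suppressWarnings(as.numeric(ids))
  ids <- if (anyNA(num)) sort(ids) else ids[order(num)]
  edges <- cbind(match(u, ids), match(v, ids))
  attributed_graph(edges = edges, n_nodes = length(ids), weights = w,
                   node_names = ids, name = basename(path))
}

read_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(ig)) {
    warning("directed GraphML input symmetrized")
    ig <- igraph::as.undirected(ig, mode = "collapse",
                                edge.attr.comb = list(weight = "sum", "first"))
  }
  n <- igraph::vcount(ig)
  el <- igraph::as_edgelist(ig, names = FALSE)
  w <- if ("weight" %in% igraph::edge_attr_names(ig)) {
    igraph::E(ig)$weight
  } else NULL
  names <- if ("name" %in% igraph::vertex_attr_names(ig)) {
    as.character(igraph::V(ig)$name)
  } else NULL
  # numeric vertex attributes (other than coordinates) become features
  feat_names <- setdiff(igraph::vertex_attr_names(ig), c("name", "label"))
  feats <- NULL
  if (n > 0 && length(feat_names) > 0) {
    cols <- Filter(is.numeric, lapply(feat_names, igraph::vertex_attr, graph = ig))
    if (length(cols) > 0) feats <- do.call(cbind, cols)
  }
  attributed_graph(edges = el, n_nodes = n, weights = w, features = feats,
                   node_names = names, name = basename(path))
}

attach_features <- function(g, features_path) {
  sep <- if (grepl("\\.tsv$", features_path)) "\t" else ","
  tab <- utils::read.table(features_path, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (!"node_id" %in% names(tab)) stop("feature table must have a node_id column")
  if (nrow(tab) != g$n_nodes) {
    stop("feature table has ", nrow(tab), " rows but graph has ", g$n_nodes,
         " nodes")
  }
  pos <- match(g$node_names, as.character(tab$node_id))
  if (anyNA(pos)) stop("feature table is missing node id(s): ",
                       paste(utils::head(g$node_names[is.na(pos)], 3), collapse = ", "))
  feats <- as.matrix(tab[pos, setdiff(names(tab), "node_id"), drop = FALSE])
  rownames(feats) <- NULL
  g$features <- feats
  storage.mode(g$features) <- "double"
  g
}

#' Write a graph or summary graph to disk
#'
#' Supports GraphML (via igraph, carrying features / aggregates as vertex
#' attributes), plain edge lists (external ids, tab-separated, with a weight
#' column when weights differ from 1) and Graphviz DOT. Summary-graph exports
#' carry cluster size, the aggregate color value and the semantic/structural
#' edge flags as attributes.
#'
#' @param g an `attributed_graph` or `summary_graph`.
#' @param path output file.
#' @param format `"graphml"`, `"edgelist"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, format = c("graphml", "edgelist", "dot")) {
  format <- match.arg(format)
  if (inherits(g, "summary_graph")) return(write_summary(g, path, format))
  if (!inherits(g, "attributed_graph")) stop("unsupported graph object")
  switch(format,
    edgelist = {
      lines <- character(0)
      if (nrow(g$edges) > 0) {
        u <- g$node_names[g$edges[, 1]]
        v <- g$node_names[g$edges[, 2]]
        lines <- if (all(g$weights == 1)) paste(u, v, sep = "\t")
                 else paste(u, v, format(g$weights, digits = 17), sep = "\t")
      }
      writeLines(lines, path)
    },
    graphml = {
      ig <- as_igraph(g)
      if (!is.null(g$features)) {
        for (j in seq_len(ncol(g$features))) {
          cn <- colnames(g$features)[j]
          if (is.null(cn) || !nzchar(cn)) cn <- paste0("f", j)
          ig <- igraph::set_vertex_attr(ig, cn, value = g$features[, j])
        }
      }
      if (!is.null(g$labels)) {
        ig <- igraph::set_vertex_attr(ig, "label_class", value = g$labels)
      }
      igraph::write_graph(ig, path, format = "graphml")
    },
    dot = {
      lines <- c("graph G {",
                 paste0("  n", seq_len(g$n_nodes) - 1L,
                        " [name=\"", g$node_names, "\"];"))
      if (nrow(g$edges) > 0) {
        lines <- c(lines, paste0("  n", g$edges[, 1] - 1L, " -- n",
                                 g$edges[, 2] - 1L, ";"))
      }
      writeLines(c(lines, "}"), path)
    }
  )
  invisible(path)
}

write_summary <- function(s, path, format) {
  switch(format,
    dot = {
      writeLines(summary_dot_lines(s, viz_spec()), path)
    },
    graphml = {
      k <- s$n_clusters
      ig <- igraph::make_empty_graph(n = k, directed = FALSE)
      if (nrow(s$edges) > 0) {
        ig <- igraph::add_edges(ig, as.integer(rbind(s$edges$from, s$edges$to)))
        ig <- igraph::set_edge_attr(ig, "semantic", value = s$edges$semantic)
        ig <- igraph::set_edge_attr(ig, "structural", value = s$edges$structural)
        ig <- igraph::set_edge_attr(ig, "shared_nodes", value = s$edges$shared_nodes)
        ig <- igraph::set_edge_attr(ig, "shared_edges", value = s$edges$shared_edges)
      }
      ig <- igraph::set_vertex_attr(ig, "size", value = s$size)
      ig <- igraph::set_vertex_attr(ig, "cover_index", value = s$cover_index)
      if (!is.null(s$mean_lens)) {
        ig <- igraph::set_vertex_attr(ig, "mean_lens", value = s$mean_lens)
      }
      if (!is.null(s$majority_label)) {
        ig <- igraph::set_vertex_attr(ig, "majority_label", value = s$majority_label)
      }
      igraph::write_graph(ig, path, format = "graphml")
    },
    edgelist = {
      lines <- character(0)
      if (nrow(s$edges) > 0) {
        lines <- paste(s$edges$from - 1L, s$edges$to - 1L, sep = "\t")
      }
      writeLines(lines, path)
    }
  )
  invisible(path)
}

#' Connected components of an induced subgraph
#'
#' Computes the connected components of the subgraph induced by a node
#' subset, the clustering step of the refined pull back cover. Blocks are
#' returned in ascending order of their minimum member so downstream cluster
#' numbering is deterministic.
#'
#' @param g an `attributed_graph`.
#' @param node_subset integer vector of internal node ids (1-based).
#' @return list of integer vectors (sorted), one per component.
#' @export
connected_components <- function(g, node_subset) {
  node_subset <- as.integer(node_subset)
  if (length(node_subset) == 0) return(list())
  if (any(node_subset < 1L) || any(node_subset > g$n_nodes)) {
    stop("node subset contains id outside 1..", g$n_nodes)
  }
  node_subset <- sort(unique(node_subset))
  sub <- igraph::induced_subgraph(as_igraph(g), node_subset)
  memb <- igraph::components(sub)$membership
  blocks <- split(node_subset, memb)
  names(blocks) <- NULL
  blocks <- lapply(blocks, sort)
  blocks[order(vapply(blocks, min, 0L))]
}
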