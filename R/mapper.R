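#' Refine pull back sets into clusters
#'
#' Splits every pull back set into clusters: either the connected components
#' of the induced subgraph (the topological choice) or a single trivial
#' cluster per nonempty set (the choice used for pooling, where the number of
#' clusters must be controlled). Empty pull back sets produce no cluster.
#' Clusters are ordered by (cover element, minimum node id).
#'
#' @param g an `attributed_graph`.
#' @param pullback list of integer node-id vectors from [hard_membership()].
#' @param clustering `"connected_components"` or `"trivial"`.
#' @return list of clusters, each a list with `cover_index`, `cluster_index`
#'   (within the cover element) and sorted `nodes`.
#' @export
refine_pullback <- function(g, pullback,
                            clustering = c("connected_components", "trivial")) {
  clustering <- match.arg(clustering)
  out <- list()
  for (i in seq_along(pullback)) {
    nodes <- pullback[[i]]
    if (length(nodes) == 0) next
    blocks <- if (clustering == "trivial") list(sort(as.integer(nodes)))
              else connected_components(g, nodes)
    for (j in seq_along(blocks)) {
      out[[length(out) + 1L]] <- list(cover_index = i, cluster_index = j,
                                      nodes = blocks[[j]])
    }
  }
  out
}

#' Extend clusters with their incident edges
#'
#' The edge-refinement step: each cluster is extended with every input-graph
#' edge that has at least one endpoint in the cluster, turning the node cover
#' into a cover of the whole graph (nodes and edges). Since the node sets
#' cover V, the incident-edge sets cover E.
#'
#' @param g an `attributed_graph`.
#' @param clusters output of [refine_pullback()].
#' @return the clusters with an `incident_edges` field (sorted row indices
#'   into `g$edges`).
#' @export
edge_refine <- function(g, clusters) {
  m <- nrow(g$edges)
  node_edges <- vector("list", g$n_nodes)
  if (m > 0) {
    es <- split(rep(seq_len(m), 2L), c(g$edges[, 1], g$edges[, 2]))
    node_edges[as.integer(names(es))] <- es
  }
  lapply(clusters, function(cl) {
    cl$incident_edges <- sort(unique(unlist(node_edges[cl$nodes])))
    if (is.null(cl$incident_edges)) cl$incident_edges <- integer(0)
    cl
  })
}

#' Nerve 1-skeleton of a (possibly edge-refined) cluster cover
#'
#' One summary node per cluster; two clusters are joined exactly when they
#' intersect. With edge refinement an intersection can happen through shared
#' nodes (a "semantic" connection: the lens maps the clusters to overlapping
#' regions) or through shared incident edges (a "structural" connection: the
#' clusters are wired together in the graph). Both flags can hold at once.
#' Self-intersections produce no self-loop.
#'
#' Each summary node carries aggregates of its members: cluster size, mean
#' lens value, feature means, and the majority node label (ties broken by the
#' smallest class id).
#'
#' @param clusters clusters from [refine_pullback()], optionally passed
#'   through [edge_refine()].
#' @param g the underlying `attributed_graph`.
#' @param lens optional `lens_values` used for the mean-lens aggregate.
#' @return an object of class `summary_graph`.
#' @export
nerve_1skeleton <- function(clusters, g, lens = NULL) {
  k <- length(clusters)
  pair_keys <- function(id_sets) {
    # id_sets: list mapping an item -> cluster ids containing it
    pairs <- list()
    for (ids in id_sets) {
      if (length(ids) < 2) next
      cmb <- utils::combn(sort(ids), 2)
      pairs[[length(pairs) + 1L]] <- cmb
    }
    if (length(pairs) == 0) return(matrix(integer(0), nrow = 2))
    do.call(cbind, pairs)
  }
  # invert node -> clusters and edge -> clusters
  node_owner <- list()
  edge_owner <- list()
  for (ci in seq_len(k)) {
    for (v in clusters[[ci]]$nodes) {
      node_owner[[as.character(v)]] <- c(node_owner[[as.character(v)]], ci)
    }
    for (e in clusters[[ci]]$incident_edges %||% integer(0)) {
      edge_owner[[as.character(e)]] <- c(edge_owner[[as.character(e)]], ci)
    }
  }
  sem <- pair_keys(node_owner)
  str <- pair_keys(edge_owner)
  count_pairs <- function(p) {
    if (ncol(p) == 0) return(integer(0))
    table(paste(p[1, ], p[2, ]))
  }
  sem_tab <- count_pairs(sem)
  str_tab <- count_pairs(str)
  keys <- union(names(sem_tab), names(str_tab))
  if (length(keys) > 0) {
    km <- do.call(rbind, strsplit(keys, " "))
    from <- as.integer(km[, 1]); to <- as.integer(km[, 2])
    ord <- order(from, to)
    edges <- data.frame(
      from = from[ord], to = to[ord],
      semantic = keys[ord] %in% names(sem_tab),
      structural = keys[ord] %in% names(str_tab),
      shared_nodes = as.integer(ifelse(is.na(sem_tab[keys[ord]]), 0L,
                                       sem_tab[keys[ord]])),
      shared_edges = as.integer(ifelse(is.na(str_tab[keys[ord]]), 0L,
                                       str_tab[keys[ord]]))
    )
  } else {
    edges <- data.frame(from = integer(0), to = integer(0),
                        semantic = logical(0), structural = logical(0),
                        shared_nodes = integer(0), shared_edges = integer(0))
  }
  # aggregates
  sizes <- vapply(clusters, function(cl) length(cl$nodes), 0L)
  mean_lens <- NULL
  if (!is.null(lens)) {
    mean_lens <- t(vapply(clusters,
                          function(cl) colMeans(lens$values[cl$nodes, , drop = FALSE]),
                          numeric(ncol(lens$values))))
    if (ncol(lens$values) == 1) mean_lens <- as.numeric(mean_lens)
  }
  feature_mean <- NULL
  if (!is.null(g$features) && ncol(g$features) > 0) {
    feature_mean <- t(vapply(clusters,
                             function(cl) colMeans(g$features[cl$nodes, , drop = FALSE]),
                             numeric(ncol(g$features))))
  }
  majority_label <- NULL
  label_fractions <- NULL
  if (!is.null(g$labels)) {
    majority_label <- vapply(clusters, function(cl) {
      tab <- table(g$labels[cl$nodes])
      cls <- as.integer(names(tab))
      best <- cls[tab == max(tab)]
      min(best)                       # ties -> smallest class id
    }, 0L)
    label_fractions <- vapply(clusters, function(cl) {
      mean(g$labels[cl$nodes] != 0)   # fraction of positive-class members
    }, 0)
  }
  structure(
    list(n_clusters = k,
         clusters = lapply(clusters, `[[`, "nodes"),
         cover_index = vapply(clusters, `[[`, 0L, "cover_index"),
         incident_edges = lapply(clusters, function(cl) cl$incident_edges %||% integer(0)),
         size = sizes, mean_lens = mean_lens, feature_mean = feature_mean,
         majority_label = majority_label, label_fraction = label_fractions,
         edges = edges, name = g$name),
    class = "summary_graph"
  )
}

#' @export
print.summary_graph <- function(x, ...) {
  cat(sprintf("summary_graph: %d clusters, %d edges (%d semantic, %d structural)\n",
              x$n_clusters, nrow(x$edges), sum(x$edges$semantic),
              sum(x$edges$structural)))
  invisible(x)
}

#' Structural graph Mapper
#'
#' The full pipeline: pull the cover back through the lens, refine each
#' preimage into clusters, extend every cluster with its incident edges, and
#' return the nerve 1-skeleton. The edge-refinement step is what makes the
#' summary *structural*: clusters connected in the input graph are joined
#' even when the lens maps them to disjoint cover elements.
#'
#' @param g an `attributed_graph`.
#' @param lens a `lens_values` over the nodes of `g`.
#' @param cover an `interval_cover` or `grid_cover` of the lens codomain.
#' @param clustering `"connected_components"` or `"trivial"`.
#' @return a `summary_graph` whose edges carry `semantic` / `structural`
#'   flags and intersection cardinalities.
#' @export
structural_mapper <- function(g, lens, cover,
                              clustering = c("connected_components", "trivial")) {
  clustering <- match.arg(clustering)
  pb <- hard_membership(lens, cover)
  cl <- refine_pullback(g, pb, clustering)
  cl <- edge_refine(g, cl)
  nerve_1skeleton(cl, g, lens)
}

#' Plain graph Mapper (node cover only)
#'
#' The classical graph Mapper: identical to [structural_mapper()] but without
#' the edge-refinement step, so summary edges can only arise from shared
#' nodes (semantic connections). Provided for comparison; its edge set is
#' always a subset of the structural summary's for the same lens, cover and
#' clustering.
#'
#' @inheritParams structural_mapper
#' @return a `summary_graph` with `structural` uniformly `FALSE`.
#' @export
plain_mapper <- function(g, lens, cover,
                         clustering = c("connected_components", "trivial")) {
  clustering <- match.arg(clustering)
  pb <- hard_membership(lens, cover)
  cl <- refine_pullback(g, pb, clustering)
  nerve_1skeleton(cl, g, lens)
}
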