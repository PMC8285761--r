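#' Visualization specification for summary graphs
#'
#' @param color_by node fill aggregate: `"mean_lens"` (average lens value,
#'   e.g. average predicted class probability), `"majority_label"` (most
#'   frequent node class), `"label_fraction"` (proportion of positive-label
#'   members) or `"feature_mean"` (first feature column mean).
#' @param size_by `"cluster_size"` (node width proportional to the square
#'   root of the member count) or `"constant"`.
#' @param colormap a `grDevices::hcl.colors` palette name.
#' @param label_nodes draw cluster sizes as node labels.
#' @return an object of class `viz_spec`.
#' @export
viz_spec <- function(color_by = c("mean_lens", "majority_label",
                                  "label_fraction", "feature_mean"),
                     size_by = c("cluster_size", "constant"),
                     colormap = "Viridis", label_nodes = TRUE) {
  structure(list(color_by = match.arg(color_by), size_by = match.arg(size_by),
                 colormap = colormap, label_nodes = label_nodes),
            class = "viz_spec")
}

summary_color_values <- function(s, spec) {
  vals <- switch(spec$color_by,
    mean_lens = if (is.matrix(s$mean_lens)) s$mean_lens[, 1] else s$mean_lens,
    majority_label = s$majority_label,
    label_fraction = s$label_fraction,
    feature_mean = if (!is.null(s$feature_mean)) s$feature_mean[, 1] else NULL
  )
  if (is.null(vals)) {
    stop("summary graph has no '", spec$color_by, "' aggregate")
  }
  as.numeric(vals)
}

# deterministic DOT text for a summary graph; color normalization is
# per-figure min-max over the cluster aggregates, recorded in the header
summary_dot_lines <- function(s, spec) {
  vals <- summary_color_values(s, spec)
  r <- range(vals)
  norm <- if (r[2] > r[1]) (vals - r[1]) / (r[2] - r[1]) else rep(0.5, length(vals))
  palette <- grDevices::hcl.colors(101, spec$colormap)
  cols <- palette[round(norm * 100) + 1]
  widths <- if (spec$size_by == "cluster_size") {
    round(0.3 * sqrt(s$size), 4)
  } else rep(0.5, s$n_clusters)
  lines <- c(
    "graph summary {",
    sprintf("  // color_by=%s normalization: min=%.10g max=%.10g",
            spec$color_by, r[1], r[2]),
    "  node [shape=circle, style=filled, fixedsize=true];",
    sprintf("  c%d [label=\"%s\", width=%.4f, fillcolor=\"%s\", size=%d, value=%.10g];",
            seq_len(s$n_clusters) - 1L,
            if (spec$label_nodes) as.character(s$size) else "",
            widths, cols, s$size, vals)
  )
  if (nrow(s$edges) > 0) {
    style <- ifelse(s$edges$structural, "solid", "dashed")
    lines <- c(lines, sprintf(
      "  c%d -- c%d [style=%s, semantic=%s, structural=%s, shared_nodes=%d, shared_edges=%d];",
      s$edges$from - 1L, s$edges$to - 1L, style,
      tolower(s$edges$semantic), tolower(s$edges$structural),
      s$edges$shared_nodes, s$edges$shared_edges))
  }
  c(lines, "}")
}

#' Render a summary graph to Graphviz DOT
#'
#' Writes a deterministic DOT file: node width proportional to the square
#' root of the cluster size, fill color from the chosen colormap over the
#' chosen aggregate (normalized per figure, recorded in a header comment),
#' solid edges for structural connections and dashed for semantic-only
#' ones. Rendering to raster is left to an external layout engine.
#'
#' @param s a `summary_graph`.
#' @param spec a [viz_spec()].
#' @param path output DOT path, or `NULL` to return the text only.
#' @return the DOT text, invisibly.
#' @export
render_summary <- function(s, spec = viz_spec(), path = NULL) {
  lines <- summary_dot_lines(s, spec)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Grid of summaries over cover resolutions and overlaps
#'
#' Multi-scale summarization: one summary per (number of cover elements,
#' overlap) combination — e.g. `n` in {16, 64, 256} by `g` in {0.1, 0.25,
#' 0.35} — written as `summary_n{n}_g{g}.dot` plus an `index.txt` listing.
#' Features that persist across resolutions are structurally stable;
#' connections that only appear at high overlap are scale-sensitive.
#'
#' @param g an `attributed_graph`.
#' @param lens a `lens_values`.
#' @param n_list cover sizes (per axis for 2-d lenses).
#' @param g_list overlap fractions.
#' @param clustering passed to [structural_mapper()].
#' @param dir output directory (created if missing), or `NULL` to skip
#'   writing.
#' @param spec a [viz_spec()] for the DOT rendering.
#' @return named list of `summary_graph` objects (`"n{n}_g{g}"`).
#' @export
hierarchical_grid <- function(g, lens, n_list = c(16L, 64L, 256L),
                              g_list = c(0.1, 0.25, 0.35),
                              clustering = "connected_components",
                              dir = NULL, spec = viz_spec()) {
  stopifnot(length(n_list) > 0, length(g_list) > 0)
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- ncol(lens$values)
  out <- list()
  files <- character(0)
  for (gv in g_list) {
    for (nv in n_list) {
      cover <- if (d == 1) {
        make_interval_cover(nv, gv, min(lens$values), max(lens$values))
      } else {
        make_grid_cover(nv, nv, gv, rbind(range(lens$values[, 1]),
                                          range(lens$values[, 2])))
      }
      s <- structural_mapper(g, lens, cover, clustering)
      key <- sprintf("n%d_g%g", nv, gv)
      out[[key]] <- s
      if (!is.null(dir)) {
        f <- file.path(dir, sprintf("summary_n%d_g%g.dot", nv, gv))
        render_summary(s, spec, f)
        files <- c(files, basename(f))
      }
    }
  }
  if (!is.null(dir)) writeLines(files, file.path(dir, "index.txt"))
  out
}
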