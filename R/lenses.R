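#' Construct a lens-values object
#'
#' A lens assigns every node a point in R^d (d = 1 or 2); the cover of the
#' lens codomain is pulled back through these values to decompose the graph.
#'
#' @param values numeric vector or N x d matrix, d in {1, 2}.
#' @param lens_name short name recorded for provenance.
#' @param metadata optional list of extra provenance (seeds, raw scores, ...).
#' @return an object of class `lens_values` with elements `values` (N x d
#'   matrix), `lens_name`, `range` (2 x d matrix of per-dimension min/max)
#'   and `metadata`.
#' @export
lens_values <- function(values, lens_name = "lens", metadata = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  dimnames(values) <- NULL
  if (!ncol(values) %in% c(1L, 2L)) stop("lens dimension must be 1 or 2")
  if (any(!is.finite(values))) stop("lens values must be finite (no NaN/Inf)")
  rng <- apply(values, 2, range)
  structure(list(values = values, lens_name = lens_name, range = rng,
                 metadata = metadata),
            class = "lens_values")
}

#' @export
print.lens_values <- function(x, ...) {
  cat(sprintf("lens_values '%s': %d nodes, d=%d, range [%.4g, %.4g]\n",
              x$lens_name, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

# Power iteration for PageRank on a (possibly weighted) symmetric adjacency.
# The undirected graph is treated as bidirected; dangling nodes (zero degree)
# redistribute their mass uniformly, keeping the transition matrix stochastic.
pagerank_scores <- function(A, damping = 0.85, tol = 1e-10, max_iter = 1000L) {
  n <- nrow(A)
  if (n == 0) stop("PageRank undefined on the empty graph")
  if (damping <= 0 || damping >= 1) stop("damping must lie in (0, 1)")
  deg <- as.numeric(Matrix::rowSums(A))
  dangling <- deg == 0
  inv_deg <- ifelse(dangling, 0, 1 / deg)
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    spread <- as.numeric(A %*% (v * inv_deg))
    v_new <- damping * (spread + sum(v[dangling]) / n) + (1 - damping) / n
    delta <- sum(abs(v_new - v))
    v <- v_new
    if (delta < tol) return(list(scores = v, iterations = it, residual = delta))
  }
  stop("PageRank did not converge in ", max_iter,
       " iterations (L1 residual ", format(delta), ")")
}

#' PageRank lens
#'
#' Scores every node by its stationary random-walk probability with uniform
#' teleport (damping factor defaults to the conventional 0.85) and rescales
#' the raw probability vector to span `[0, 1]`, so that an interval cover of
#' the unit interval is fully used. The raw scores (which sum to 1) are kept
#' in `metadata$raw`.
#'
#' @param g an `attributed_graph` with at least one node.
#' @param damping teleport damping factor in (0, 1).
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return a `lens_values` (d = 1) in `[0, 1]`.
#' @export
pagerank_lens <- function(g, damping = 0.85, tol = 1e-10, max_iter = 1000L) {
  pr <- pagerank_scores(g$adjacency, damping, tol, max_iter)
  lens_values(minmax_rescale(pr$scores), "pagerank",
              metadata = list(raw = pr$scores, damping = damping,
                              iterations = pr$iterations,
                              residual = pr$residual))
}

# min-max rescale to [0,1]; a constant vector maps to the midpoint 0.5
minmax_rescale <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= 0) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Fiedler-vector lens
#'
#' The eigenvector of the graph Laplacian `L = D - A` for the second-smallest
#' eigenvalue. Its sign pattern gives the spectral bipartition of the graph,
#' which the Mapper construction reproduces with a two-interval cover around
#' zero. The returned vector has unit Euclidean norm, is orthogonal to the
#' constant vector, and its sign is fixed so that the lowest-id node with a
#' nonzero entry is positive.
#'
#' @param g a connected `attributed_graph` with at least 2 nodes.
#' @return a `lens_values` (d = 1) with `metadata$lambda2`.
#' @export
fiedler_lens <- function(g) {
  if (g$n_nodes < 2) stop("Fiedler vector requires at least 2 nodes")
  comp <- connected_components(g, seq_len(g$n_nodes))
  if (length(comp) > 1) {
    stop("graph is disconnected (lambda2 = 0); e.g. components {",
         paste(comp[[1]], collapse = ","), "} and {",
         paste(comp[[2]], collapse = ","), "}")
  }
  A <- as.matrix(g$adjacency)
  L <- diag(rowSums(A)) - A
  e <- eigen(L, symmetric = TRUE)
  n <- g$n_nodes
  lambda2 <- e$values[n - 1]        # eigen() sorts decreasing
  v <- e$vectors[, n - 1]
  v <- v / sqrt(sum(v^2))
  nz <- which(abs(v) > 1e-8)
  if (length(nz) > 0 && v[nz[1]] < 0) v <- -v
  lens_values(v, "fiedler", metadata = list(lambda2 = lambda2))
}

#' Graph-density lens
#'
#' `f(v) = sum_u exp(-D(u, v) / scale)` where `D` is the unweighted
#' shortest-path hop distance. The self term `D(v, v) = 0` contributes 1;
#' unreachable pairs contribute 0 (the continuous limit of `exp(-Inf)`).
#' Central, well-connected nodes score high.
#'
#' @param g an `attributed_graph`.
#' @param scale positive length scale of the exponential decay (hops).
#' @return a `lens_values` (d = 1).
#' @export
density_lens <- function(g, scale) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive")
  D <- igraph::distances(as_igraph(g), weights = NA)
  lens_values(rowSums(exp(-D / scale)), "density",
              metadata = list(scale = scale))
}

#' Embedding lens with a pluggable reducer
#'
#' Reduces precomputed node embeddings (e.g. from an unsupervised graph
#' representation model) to 1 or 2 lens dimensions through an injected
#' dimensionality-reduction function.
#'
#' @param embeddings N x d' numeric matrix of node embeddings.
#' @param reducer function `(matrix, d) -> N x d matrix`; see
#'   [reducer_identity()] and [reducer_pca()].
#' @param d target lens dimension, 1 or 2.
#' @return a `lens_values` recording the reducer name in its metadata.
#' @export
embedding_lens <- function(embeddings, reducer = reducer_identity(), d = 2L) {
  embeddings <- as.matrix(embeddings)
  if (anyNA(embeddings) || any(!is.finite(embeddings))) {
    stop("embeddings contain NaN/Inf")
  }
  d <- as.integer(d)
  if (!d %in% c(1L, 2L)) stop("lens dimension d must be 1 or 2")
  red <- reducer(embeddings, d)
  red <- as.matrix(red)
  if (ncol(red) != d) stop("reducer returned ", ncol(red), " columns, expected ", d)
  lens_values(red, paste0("embedding:", attr(reducer, "reducer_name") %||% "custom"),
              metadata = list(reducer = attr(reducer, "reducer_name"),
                              seed = attr(reducer, "seed")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Identity reducer
#'
#' Returns the first `d` embedding columns unchanged.
#' @return a reducer function for [embedding_lens()].
#' @export
reducer_identity <- function() {
  f <- function(x, d) {
    if (ncol(x) < d) stop("embeddings have fewer than ", d, " columns")
    x[, seq_len(d), drop = FALSE]
  }
  attr(f, "reducer_name") <- "identity"
  f
}

#' PCA reducer
#'
#' Projects embeddings onto their first `d` principal components
#' (deterministic; no seed needed).
#' @return a reducer function for [embedding_lens()].
#' @export
reducer_pca <- function() {
  f <- function(x, d) {
    if (ncol(x) == 1 || stats::sd(as.numeric(x)) == 0) {
      # degenerate variance: fall back to (centered) raw columns
      out <- scale(x[, rep_len(seq_len(ncol(x)), d), drop = FALSE],
                   scale = FALSE)
      return(matrix(as.numeric(out), ncol = d))
    }
    p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(d, ncol(p$x))
    out <- p$x[, seq_len(k), drop = FALSE]
    if (k < d) out <- cbind(out, matrix(0, nrow(out), d - k))
    out
  }
  attr(f, "reducer_name") <- "pca"
  f
}

#' Supervised probability lens
#'
#' For a binary node classifier, the predicted probability of the positive
#' class is itself a lens into `[0, 1]` — the setting used for supervised
#' summary visualizations.
#'
#' @param probabilities N x 2 matrix of class probabilities; rows must sum to
#'   1 within 1e-6.
#' @param positive column index of the positive class (default 2).
#' @return a `lens_values` (d = 1) in `[0, 1]`.
#' @export
supervised_prob_lens <- function(probabilities, positive = 2L) {
  probabilities <- as.matrix(probabilities)
  if (ncol(probabilities) != 2) stop("expected a binary (N x 2) probability table")
  if (any(abs(rowSums(probabilities) - 1) > 1e-6)) {
    stop("probability rows must sum to 1 (within 1e-6)")
  }
  lens_values(probabilities[, positive], "supervised_prob",
              metadata = list(positive = positive))
}
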