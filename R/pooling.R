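#' Construct a soft cluster assignment
#'
#' An N x K row-stochastic matrix S whose entry `S[i, j]` is the probability
#' that node i belongs to cluster j. Pooling methods built on such matrices
#' coarsen a graph via `A' = S^T (A + I) S`, `X' = S^T X`.
#'
#' @param S nonnegative numeric matrix with rows summing to 1 (within 1e-9).
#' @param method one of `"mpr"`, `"dmp"`, `"external"`.
#' @param provenance optional list describing the lens/cover that produced S.
#' @return an object of class `soft_assignment`.
#' @export
soft_assignment <- function(S, method = c("external", "mpr", "dmp"),
                            provenance = list()) {
  method <- match.arg(method)
  S <- as.matrix(S)
  if (any(S < 0)) stop("assignment matrix must be nonnegative")
  rs <- rowSums(S)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("assignment rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  structure(list(S = S, K = ncol(S), method = method, provenance = provenance),
            class = "soft_assignment")
}

#' @export
print.soft_assignment <- function(x, ...) {
  cat(sprintf("soft_assignment (%s): %d nodes -> %d clusters\n", x$method,
              nrow(x$S), x$K))
  invisible(x)
}

# membership sets -> normalized indicator matrix (Eq.-3-style assignment)
membership_to_assignment <- function(sets, n_nodes) {
  K <- length(sets)
  S <- matrix(0, n_nodes, K)
  for (j in seq_len(K)) S[sets[[j]], j] <- 1
  S / rowSums(S)
}

# MPR assignment from a raw adjacency matrix (used on pooled, weighted,
# possibly self-looped graphs during hierarchical pooling)
mpr_assignment_from_adjacency <- function(A, n_clusters, overlap_g,
                                          damping = 0.85) {
  pr <- pagerank_scores(A, damping = damping)
  lens <- lens_values(minmax_rescale(pr$scores), "pagerank")
  cover <- make_interval_cover(n_clusters, overlap_g, 0, 1)
  memb <- hard_membership(lens, cover)
  soft_assignment(membership_to_assignment(memb, nrow(A)), method = "mpr",
                  provenance = list(lens = lens, cover = cover))
}

#' Mapper/PageRank (MPR) soft cluster assignment
#'
#' The fixed-lens pooling operator: nodes are scored by the PageRank lens,
#' an interval cover of `[0, 1]` is pulled back, and each node's assignment
#' row is the uniform distribution over the cover elements containing it
#' (a one-hot row when the node lies in a single element, `1/2, 1/2` on an
#' overlap). Clusters therefore group nodes of similar PageRank: the few
#' highly connected hubs pool together, as do the many low-score dangling
#' nodes. Cover elements containing no node yield all-zero columns, which
#' are retained here and dropped just before pooling in
#' [hierarchical_pool()].
#'
#' @param g an `attributed_graph`.
#' @param n_clusters number of interval cover elements (K).
#' @param overlap_g interval overlap fraction in `[0, 1)`.
#' @param damping PageRank damping factor.
#' @return a `soft_assignment` with `method = "mpr"`.
#' @export
mpr_assignment <- function(g, n_clusters, overlap_g = 0.25, damping = 0.85) {
  mpr_assignment_from_adjacency(g$adjacency, n_clusters, overlap_g, damping)
}

#' Differentiable Mapper (DMP) soft cluster assignment
#'
#' The differentiable pooling operator: lens values are squashed into
#' `[0, 1]` by a sigmoid and softly assigned to the RBF kernels of the cover,
#' `S[i, j] = phi(sigmoid(f_i), x_j) / sum_j phi(sigmoid(f_i), x_j)`. Rows
#' sum to 1 by construction. Because a point on a line can only be close to
#' a few kernel centers, the assignment has low entropy whenever the scale
#' `delta` is small — the low-entropy behaviour is obtained topologically
#' rather than through a loss term.
#'
#' Kernel values are floored at 1e-300 before normalization; if every kernel
#' in a row underflows (tiny `delta`), the row is renormalized over the
#' floored values with a warning.
#'
#' @param lens a `lens_values` with d = 1 (e.g. one GNN output channel).
#' @param cover an `rbf_cover`.
#' @return a `soft_assignment` with `method = "dmp"`.
#' @export
dmp_assignment <- function(lens, cover) {
  stopifnot(inherits(cover, "rbf_cover"))
  if (ncol(lens$values) != 1) stop("DMP requires a 1-dimensional lens")
  z <- 1 / (1 + exp(-lens$values[, 1]))
  K <- rbf_kernel_values(cover, z)
  if (any(apply(K, 1, max) < 1e-300)) {
    warning("RBF kernels underflowed for some rows; flooring at 1e-300")
  }
  K <- pmax(K, 1e-300)
  S <- K / rowSums(K)
  soft_assignment(S, method = "dmp",
                  provenance = list(lens = lens, cover = cover))
}

#' Pool a graph through a soft assignment
#'
#' Computes the coarsened adjacency `A' = S^T (A + I) S` and features
#' `X' = S^T X` by sparse products. The identity term adds self-loops before
#' pooling, so two clusters end up connected exactly when they share an edge
#' of `A + I` — i.e. share an input edge or a common node. The diagonal of
#' `A'` is kept as self-loop weight.
#'
#' @param S a `soft_assignment` (or bare N x K matrix).
#' @param g an `attributed_graph`, or a square adjacency matrix (dense or
#'   sparse) for already-pooled graphs.
#' @param features optional feature matrix overriding `g$features`.
#' @return an object of class `pooled_graph` with `adjacency` (K x K dense
#'   matrix), `features` (K x k or NULL) and `assignment`.
#' @export
pool <- function(S, g, features = NULL) {
  Sm <- if (inherits(S, "soft_assignment")) S$S else as.matrix(S)
  if (inherits(g, "attributed_graph")) {
    A <- g$adjacency
    if (is.null(features)) features <- g$features
  } else {
    A <- g
  }
  if (nrow(Sm) != nrow(A)) {
    stop("assignment has ", nrow(Sm), " rows but graph has ", nrow(A), " nodes")
  }
  Ahat <- A + Matrix::Diagonal(nrow(A))
  Ap <- as.matrix(Matrix::t(Sm) %*% Ahat %*% Sm)
  Xp <- if (!is.null(features)) as.matrix(Matrix::t(Sm) %*% features) else NULL
  structure(list(adjacency = Ap, features = Xp,
                 assignment = if (inherits(S, "soft_assignment")) S else
                   soft_assignment(Sm)),
            class = "pooled_graph")
}

#' @export
print.pooled_graph <- function(x, ...) {
  cat(sprintf("pooled_graph: %d clusters, %d nonzero off-diagonal entries\n",
              nrow(x$adjacency),
              sum(x$adjacency != 0) - sum(diag(x$adjacency) != 0)))
  invisible(x)
}

#' Nerve summary of a soft assignment
#'
#' The executable form of the equivalence between soft-cluster pooling and
#' the structural Mapper: treat the support of each assignment column as a
#' pull back set (node v belongs to cover element i iff `S[v, i] > 0`), apply
#' trivial clustering and edge refinement, and take the nerve. The resulting
#' edge set coincides with the off-diagonal nonzero pattern of
#' `S^T (A + I) S` over the nonempty columns; empty columns (all-zero)
#' produce no nerve vertex and their `A'` rows/columns are identically zero.
#'
#' @param S a `soft_assignment` (or bare matrix).
#' @param g an `attributed_graph`.
#' @return a `summary_graph`; `cover_index` records the originating column
#'   of S for each cluster.
#' @export
assignment_to_nerve <- function(S, g) {
  Sm <- if (inherits(S, "soft_assignment")) S$S else as.matrix(S)
  pullback <- lapply(seq_len(ncol(Sm)), function(j) which(Sm[, j] > 0))
  cl <- refine_pullback(g, pullback, clustering = "trivial")
  cl <- edge_refine(g, cl)
  nerve_1skeleton(cl, g)
}

#' Hierarchical pooling
#'
#' Applies assignment + pooling repeatedly over a decreasing schedule of
#' cover sizes (e.g. `c(20, 5)`), producing one pooled graph per level. For
#' MPR the PageRank lens is recomputed at every level on the current pooled
#' adjacency (weighted, self-loops included); for DMP the level lens is
#' produced by `lens_fun(A, X)` (default: row means of the current features)
#' and the RBF scale defaults to `1 / K^2` per level. Empty assignment
#' columns are dropped before pooling (the effective K is reported); a level
#' whose requested K is not below the current node count is skipped with a
#' warning.
#'
#' @param g an `attributed_graph`.
#' @param method `"mpr"` or `"dmp"`.
#' @param cover_sizes decreasing integer vector of per-level cover sizes.
#' @param overlap interval overlap fraction for MPR.
#' @param delta optional RBF scale for DMP (default `1 / K^2` per level).
#' @param lens_fun for DMP: function `(adjacency, features) -> numeric`
#'   giving the level lens; default `rowMeans(features)`.
#' @return list of `pooled_graph` objects, one per executed level, each with
#'   an `effective_k` field.
#' @export
hierarchical_pool <- function(g, method = c("mpr", "dmp"), cover_sizes,
                              overlap = 0.25, delta = NULL, lens_fun = NULL) {
  method <- match.arg(method)
  if (any(diff(cover_sizes) > 0)) stop("cover_sizes must be non-increasing")
  A <- g$adjacency
  X <- g$features
  if (method == "dmp" && is.null(lens_fun)) {
    if (is.null(X)) stop("DMP hierarchical pooling needs features or a lens_fun")
    lens_fun <- function(A, X) rowMeans(X)
  }
  out <- list()
  for (K in cover_sizes) {
    n_cur <- nrow(A)
    if (K >= n_cur) {
      warning("level with K = ", K, " skipped: current graph has only ",
              n_cur, " nodes")
      next
    }
    S <- if (method == "mpr") {
      mpr_assignment_from_adjacency(A, K, overlap)
    } else {
      lv <- lens_values(lens_fun(A, X), "dmp_level_lens")
      dmp_assignment(lv, make_rbf_cover(K, delta %||% (1 / K^2)))
    }
    keep <- colSums(S$S) > 0
    Sm <- S$S[, keep, drop = FALSE]
    p <- pool(soft_assignment(Sm, method = S$method, provenance = S$provenance),
              A, features = X)
    p$effective_k <- ncol(Sm)
    p$requested_k <- K
    out[[length(out) + 1L]] <- p
    A <- Matrix::Matrix(p$adjacency, sparse = TRUE)
    X <- p$features
  }
  out
}
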