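# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense matrix algebra and explicit breadth-first
# search only.

# dense PageRank power iteration on a symmetric adjacency matrix
oracle_pagerank <- function(A, damping = 0.85, tol = 1e-12, max_iter = 10000) {
  A <- as.matrix(A)
  n <- nrow(A)
  deg <- rowSums(A)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    P[i, ] <- if (deg[i] > 0) A[i, ] / deg[i] else rep(1 / n, n)
  }
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    v_new <- damping * as.numeric(t(P) %*% v) + (1 - damping) / n
    if (sum(abs(v_new - v)) < tol) return(v_new)
    v <- v_new
  }
  v
}

# breadth-first-search connected components of the subgraph induced by a
# node subset; returns blocks sorted by minimum member
oracle_components <- function(g, subset) {
  subset <- sort(unique(as.integer(subset)))
  A <- as.matrix(g$adjacency)[subset, subset, drop = FALSE] != 0
  n <- length(subset)
  seen <- rep(FALSE, n)
  blocks <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    comp <- integer(0)
    seen[s] <- TRUE
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      nb <- which(A[u, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    blocks[[length(blocks) + 1L]] <- sort(subset[comp])
  }
  blocks[order(vapply(blocks, min, 0L))]
}

# naive dense evaluation of one GCN layer
oracle_gcn <- function(X, A, W, relu = TRUE) {
  A <- as.matrix(A)
  Ahat <- A + diag(nrow(A))
  d <- rowSums(Ahat)
  N <- diag(1 / sqrt(d)) %*% Ahat %*% diag(1 / sqrt(d))
  out <- N %*% as.matrix(X) %*% as.matrix(W)
  if (relu) pmax(out, 0) else out
}

# small random graph helper (isolated nodes allowed)
random_graph <- function(n, p = 0.3, seed = 0, features = FALSE) {
  g <- standard_graph("random_gnp", n, p = p, seed = seed)
  if (features) {
    g$features <- cbind(rep(1, n), node_degrees(g))
  }
  g
}

# random sparsified row-stochastic assignment matrix
random_assignment <- function(n, K, sparsity = 0.5) {
  S <- matrix(stats::runif(n * K), n, K)
  S[matrix(stats::runif(n * K) < sparsity, n, K)] <- 0
  empty <- rowSums(S) == 0
  if (any(empty)) {
    S[cbind(which(empty), sample.int(K, sum(empty), replace = TRUE))] <- 1
  }
  S / rowSums(S)
}

# symmetric edge pattern implied by a summary graph's nerve over the
# original assignment columns
nerve_pattern <- function(nv, K) {
  M <- matrix(FALSE, K, K)
  ci <- nv$cover_index
  if (nrow(nv$edges) > 0) {
    for (r in seq_len(nrow(nv$edges))) {
      a <- ci[nv$edges$from[r]]
      b <- ci[nv$edges$to[r]]
      M[a, b] <- TRUE
      M[b, a] <- TRUE
    }
  }
  M
}

# off-diagonal nonzero pattern of a pooled adjacency
pooled_pattern <- function(Ap) {
  P <- Ap != 0
  diag(P) <- FALSE
  unname(P)
}

expect_same_blocks <- function(got, want) {
  expect_equal(lapply(got, as.integer), lapply(want, as.integer))
}

# first `count` connected two-block SBM instances; the Fiedler construction
# requires lambda2 > 0, i.e. a connected graph, so disconnected draws are
# rejected
connected_sbms <- function(count, block, p_in, p_out, seed_start = 1) {
  out <- list()
  seed <- seed_start
  while (length(out) < count) {
    g <- standard_graph("sbm", c(block, block), p_in = p_in, p_out = p_out,
                        seed = seed)
    if (length(connected_components(g, seq_len(g$n_nodes))) == 1) {
      out[[length(out) + 1L]] <- g
    }
    seed <- seed + 1L
  }
  out
}
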