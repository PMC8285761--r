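#' Graph convolutional layer forward pass
#'
#' One layer of the standard graph convolution
#' `X_{l+1} = act(D^{-1/2} (A + I) D^{-1/2} X_l W_l)`, where the identity
#' term adds self-loops and `D` is the degree matrix of the self-looped
#' (possibly weighted) adjacency, so every node has positive degree.
#'
#' @param X N x k_in feature matrix.
#' @param A N x N adjacency (dense or sparse; weighted allowed).
#' @param W k_in x k_out weight matrix.
#' @param activation `"relu"` or `"identity"`.
#' @return N x k_out feature matrix.
#' @export
gcn_forward <- function(X, A, W, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  X <- as.matrix(X); W <- as.matrix(W)
  out <- normalized_adjacency(A) %*% X %*% W
  out <- as.matrix(out)
  if (activation == "relu") out <- pmax(out, 0)
  if (any(!is.finite(out))) stop("non-finite output in GCN layer")
  out
}

# D^{-1/2} (A + I) D^{-1/2} with D the self-looped degree
normalized_adjacency <- function(A) {
  Ahat <- A + Matrix::Diagonal(nrow(A))
  d <- as.numeric(Matrix::rowSums(Ahat))
  Dinv <- Matrix::Diagonal(x = 1 / sqrt(d))
  Dinv %*% Ahat %*% Dinv
}

#' Mean readout and linear classification
#'
#' Graph-level prediction: feature-wise node average, a linear layer, and a
#' softmax, `y = softmax(mean_i(X_i) W_f + b_f)`. Invariant to node
#' permutation and to node duplication.
#'
#' @param X N x k node-feature matrix (N >= 1).
#' @param Wf k x C readout weight matrix.
#' @param bf length-C bias.
#' @return length-C probability vector summing to 1.
#' @export
readout_classify <- function(X, Wf, bf) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("cannot classify an empty graph")
  z <- as.numeric(colMeans(X) %*% as.matrix(Wf)) + as.numeric(bf)
  softmax(z)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Bundle classifier parameters
#'
#' @param embed_layers list of layers, each `list(W = matrix,
#'   activation = "relu"|"identity")`, applied on the input graph.
#' @param classify_layers list of layers applied after the first pooling.
#' @param Wf,bf readout weights and bias.
#' @return an object of class `classifier_params`.
#' @export
classifier_params <- function(embed_layers, classify_layers, Wf, bf) {
  structure(list(embed_layers = embed_layers, classify_layers = classify_layers,
                 Wf = as.matrix(Wf), bf = as.numeric(bf)),
            class = "classifier_params")
}

#' Classify a graph with the embed-pool-classify architecture
#'
#' Runs the embedding GCN stack on the input graph, coarsens with the
#' configured pooling operator, runs the classification GCN stack on the
#' pooled graph, applies any remaining pooling levels, and finishes with the
#' mean readout. Deterministic given parameters.
#'
#' @param g an `attributed_graph` with features.
#' @param params a `classifier_params`.
#' @param pooling list: `method` ("mpr" or "dmp"), `cover_sizes` (integer
#'   vector), `overlap` (MPR), `delta` (DMP, optional).
#' @return length-C probability vector.
#' @export
classify_graph <- function(g, params, pooling = list(method = "mpr",
                                                     cover_sizes = c(4L, 1L),
                                                     overlap = 0.25)) {
  if (is.null(g$features)) stop("classify_graph requires node features")
  plan <- pooling_plan(g, pooling)
  forward_probs(g$features, plan, params)
}

# Precompute everything that does not depend on the weights: the normalized
# adjacency of the input graph, the (fixed) assignment matrices of every
# pooling level and the normalized adjacencies of the pooled graphs. MPR
# assignments depend only on graph structure, never on the features, so the
# whole plan is weight-independent and gradients never flow through pooling.
pooling_plan <- function(g, pooling) {
  method <- pooling$method %||% "mpr"
  sizes <- pooling$cover_sizes %||% c(4L, 1L)
  overlap <- pooling$overlap %||% 0.25
  A <- g$adjacency
  norms <- list(normalized_adjacency(A))
  Ss <- list()
  for (K in sizes) {
    S <- if (method == "mpr") {
      mpr_assignment_from_adjacency(A, K, overlap)
    } else {
      lv <- lens_values(minmax_rescale(as.numeric(Matrix::rowSums(A))),
                        "degree")
      dmp_assignment(lv, make_rbf_cover(K, pooling$delta %||% (1 / K^2)))
    }
    keep <- colSums(S$S) > 0
    Sm <- S$S[, keep, drop = FALSE]
    Ap <- as.matrix(Matrix::t(Sm) %*% (A + Matrix::Diagonal(nrow(A))) %*% Sm)
    Ss[[length(Ss) + 1L]] <- Sm
    A <- Matrix::Matrix(Ap, sparse = TRUE)
    norms[[length(norms) + 1L]] <- normalized_adjacency(A)
  }
  list(norms = norms, assignments = Ss)
}

# internal: apply a layer given the prenormalized operator D^-1/2 Â D^-1/2
apply_layer <- function(H, Nhat, W, activation) {
  out <- as.matrix(Nhat %*% H %*% W)
  if (activation == "relu") out <- pmax(out, 0)
  if (any(!is.finite(out))) stop("non-finite output in GCN layer")
  out
}

# forward pass through embed layers -> pool -> classify layers -> remaining
# pools -> readout; plan$norms[[l]] is the normalized operator of level l
forward_probs <- function(X, plan, params) {
  H <- as.matrix(X)
  for (ly in params$embed_layers) {
    H <- apply_layer(H, plan$norms[[1]], ly$W, ly$activation)
  }
  n_lev <- length(plan$assignments)
  if (n_lev >= 1) {
    H <- as.matrix(t(plan$assignments[[1]]) %*% H)
    for (ly in params$classify_layers) {
      H <- apply_layer(H, plan$norms[[2]], ly$W, ly$activation)
    }
    level <- 2L
    while (level <= n_lev) {
      H <- as.matrix(t(plan$assignments[[level]]) %*% H)
      level <- level + 1L
    }
  } else {
    for (ly in params$classify_layers) {
      H <- apply_layer(H, plan$norms[[1]], ly$W, ly$activation)
    }
  }
  readout_classify(H, params$Wf, params$bf)
}
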