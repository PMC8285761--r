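# Seeded synthetic-graph generators. Every generator draws from its own
# seeded stream (withr::with_seed), leaving the global RNG untouched, so the
# same config + seed always yields an identical graph.

#' Synthetic spammer network
#'
#' A two-class social network: a small set of spammers connects
#' indiscriminately to any node with probability `p_spam`, while normal
#' users only connect within one of `n_communities` small communities with
#' probability `p_comm`. Spammers therefore sit at the hub of the network
#' and have markedly higher expected degree; non-spammers form many small,
#' loosely connected communities. Node features are the degree plus a noisy
#' one-hot encoding of the label (10% label flips), labelled synthetic
#' throughout.
#'
#' @param n_spam,n_normal class sizes (>= 1 each).
#' @param p_spam spammer attachment probability.
#' @param p_comm within-community attachment probability; a warning is given
#'   when `p_spam <= p_comm`.
#' @param n_communities number of normal-user communities.
#' @param seed integer seed.
#' @return an `attributed_graph` with binary labels (1 = spammer).
#' @export
spammer_graph <- function(n_spam = 20L, n_normal = 180L, p_spam = 0.3,
                          p_comm = 0.2, n_communities = 15L, seed = 0L) {
  if (n_spam < 1 || n_normal < 1) stop("both classes must be nonempty")
  if (any(c(p_spam, p_comm) < 0) || any(c(p_spam, p_comm) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  if (p_spam <= p_comm) {
    warning("p_spam <= p_comm: spammers will not be hubs")
  }
  n <- n_spam + n_normal
  withr::with_seed(seed, {
    labels <- c(rep(1L, n_spam), rep(0L, n_normal))
    community <- c(rep(NA_integer_, n_spam),
                   rep_len(seq_len(n_communities), n_normal))
    pairs <- utils::combn(n, 2)
    u <- pairs[1, ]; v <- pairs[2, ]
    spam_pair <- labels[u] == 1L | labels[v] == 1L
    same_comm <- !spam_pair & community[u] == community[v]
    p <- ifelse(spam_pair, p_spam, ifelse(same_comm, p_comm, 0))
    keep <- stats::runif(length(p)) < p
    edges <- cbind(u[keep], v[keep])
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
    flip <- stats::runif(n) < 0.1
    noisy <- ifelse(flip, 1L - labels, labels)
    features <- cbind(degree = deg,
                      class0 = as.numeric(noisy == 0L),
                      class1 = as.numeric(noisy == 1L))
    attributed_graph(edges = edges, n_nodes = n, features = features,
                     labels = labels, name = "synthetic_spammer")
  })
}

#' Standard deterministic and seeded test graphs
#'
#' Ring (cycle), path, star (one hub plus leaves), barbell (two cliques
#' joined by a single bridge edge), two-or-more-block stochastic block model
#' and Erdos-Renyi G(n, p). The first four are deterministic; the SBM and
#' G(n, p) are seeded.
#'
#' @param kind one of `"ring"`, `"path"`, `"star"`, `"barbell"`, `"sbm"`,
#'   `"random_gnp"`.
#' @param sizes integer sizes: node count for ring/path, leaf count for
#'   star, the two clique sizes for barbell, block sizes for sbm, node count
#'   for random_gnp.
#' @param p_in,p_out SBM within/between-block probabilities.
#' @param p edge probability for `random_gnp`.
#' @param seed integer seed (sbm / random_gnp only).
#' @return an `attributed_graph`.
#' @export
standard_graph <- function(kind = c("ring", "path", "star", "barbell", "sbm",
                                    "random_gnp"),
                           sizes, p_in = 0.8, p_out = 0.1, p = 0.3,
                           seed = 0L) {
  kind <- match.arg(kind)
  switch(kind,
    ring = {
      n <- sizes[1]
      stopifnot(n >= 3)
      attributed_graph(cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L)),
                       n_nodes = n, name = "ring")
    },
    path = {
      n <- sizes[1]
      stopifnot(n >= 1)
      e <- if (n > 1) cbind(seq_len(n - 1), seq_len(n - 1) + 1L) else NULL
      attributed_graph(e, n_nodes = n, name = "path")
    },
    star = {
      k <- sizes[1]
      attributed_graph(cbind(1L, seq_len(k) + 1L), n_nodes = k + 1L,
                       name = "star")
    },
    barbell = {
      m1 <- sizes[1]; m2 <- sizes[2]
      stopifnot(m1 >= 2, m2 >= 2)
      clique <- function(ids) if (length(ids) < 2) NULL else t(utils::combn(ids, 2))
      e <- rbind(clique(seq_len(m1)), clique(m1 + seq_len(m2)),
                 c(m1, m1 + 1L))           # bridge between the cliques
      attributed_graph(e, n_nodes = m1 + m2, name = "barbell")
    },
    sbm = {
      blocks <- rep(seq_along(sizes), sizes)
      n <- sum(sizes)
      withr::with_seed(seed, {
        pairs <- utils::combn(n, 2)
        same <- blocks[pairs[1, ]] == blocks[pairs[2, ]]
        pr <- ifelse(same, p_in, p_out)
        keep <- stats::runif(length(pr)) < pr
        attributed_graph(cbind(pairs[1, keep], pairs[2, keep]), n_nodes = n,
                         labels = blocks - 1L, name = "sbm")
      })
    },
    random_gnp = {
      n <- sizes[1]
      withr::with_seed(seed, {
        if (n < 2) return(attributed_graph(NULL, n_nodes = n, name = "gnp"))
        pairs <- utils::combn(n, 2)
        keep <- stats::runif(ncol(pairs)) < p
        attributed_graph(cbind(pairs[1, keep], pairs[2, keep]), n_nodes = n,
                         name = "gnp")
      })
    }
  )
}

#' Synthetic graph-classification dataset
#'
#' A balanced two-class dataset standing in for external molecular/social
#' benchmarks: class 0 graphs are rings of 10-20 nodes, class 1 graphs are
#' two-block stochastic block models of matched size (`p_in = 0.8`,
#' `p_out = 0.1`). Node features are a constant column and the node degree,
#' so the classes are separable from degree statistics alone.
#'
#' @param n_graphs even number of graphs.
#' @param seed integer seed.
#' @return a `graph_dataset` with balanced 0/1 labels.
#' @export
classification_dataset <- function(n_graphs = 100L, seed = 0L) {
  if (n_graphs %% 2 != 0) stop("n_graphs must be even for balanced classes")
  half <- n_graphs %/% 2
  withr::with_seed(seed, {
    graph_seeds <- sample.int(1e6, n_graphs)
    sizes <- sample(10:20, n_graphs, replace = TRUE)
  })
  with_degree_features <- function(g) {
    g$features <- cbind(const = rep(1, g$n_nodes), degree = node_degrees(g))
    g
  }
  graphs <- vector("list", n_graphs)
  labels <- integer(n_graphs)
  for (i in seq_len(n_graphs)) {
    if (i <= half) {
      graphs[[i]] <- standard_graph("ring", sizes[i])
      labels[i] <- 0L
    } else {
      sz <- sizes[i]
      b1 <- sz %/% 2
      graphs[[i]] <- standard_graph("sbm", c(b1, sz - b1), p_in = 0.8,
                                    p_out = 0.1, seed = graph_seeds[i])
      labels[i] <- 1L
    }
    graphs[[i]] <- with_degree_features(graphs[[i]])
  }
  # interleave classes so any contiguous split stays balanced
  ord <- order(rep(seq_len(half), 2), rep(c(0, 1), each = half))
  graph_dataset(graphs[ord], labels[ord], split_seed = seed)
}
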