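test_that("GCN layer matches hand evaluation and the dense oracle", {
  # edgeless graph: operator is the identity, layer reduces to act(XW)
  X <- matrix(c(-1, 2), 2, 1)
  A0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(2, 2))
  expect_equal(gcn_forward(X, A0, matrix(1), "relu"), matrix(c(0, 2), 2, 1))

  # single edge, unit weight: hand evaluation gives (0.5, 0.5)
  X1 <- matrix(c(1, 0), 2, 1)
  A1 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1)
  expect_equal(gcn_forward(X1, A1, matrix(1), "identity"),
               matrix(c(0.5, 0.5), 2, 1))

  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(3:12, 1); k <- sample(1:4, 1); ko <- sample(1:4, 1)
      g <- random_graph(n, p = 0.35, seed = seed + 500)
      X <- matrix(stats::rnorm(n * k), n, k)
      W <- matrix(stats::rnorm(k * ko), k, ko)
      expect_equal(gcn_forward(X, g$adjacency, W, "relu"),
                   oracle_gcn(X, g$adjacency, W, relu = TRUE),
                   tolerance = 1e-10)
    })
  }
})

test_that("GCN layer is permutation equivariant", {
  g <- random_graph(9, p = 0.4, seed = 3)
  X <- withr::with_seed(1, matrix(stats::rnorm(18), 9, 2))
  W <- withr::with_seed(2, matrix(stats::rnorm(6), 2, 3))
  out <- gcn_forward(X, g$adjacency, W)
  perm <- withr::with_seed(5, sample.int(9))
  gp <- attributed_graph(cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]), 9)
  Xp <- X
  Xp[perm, ] <- X
  outp <- gcn_forward(Xp, gp$adjacency, W)
  expect_equal(outp[perm, ], out, tolerance = 1e-12)
})

test_that("readout is a permutation/duplication-invariant softmax", {
  X <- withr::with_seed(7, matrix(stats::rnorm(12), 4, 3))
  Wf <- withr::with_seed(8, matrix(stats::rnorm(6), 3, 2))
  p <- readout_classify(X, Wf, c(0.1, -0.2))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # zero weights: uniform prediction
  expect_equal(readout_classify(X, matrix(0, 3, 2), c(0, 0)), c(0.5, 0.5))
  # duplicating every node leaves the mean, hence the output, unchanged
  expect_equal(readout_classify(rbind(X, X), Wf, c(0.1, -0.2)), p,
               tolerance = 1e-12)
  expect_error(readout_classify(X[0, , drop = FALSE], Wf, c(0, 0)), "empty")
})

demo_params <- function(k_in = 2, hidden = 4, n_classes = 2, seed = 1) {
  withr::with_seed(seed, {
    classifier_params(
      embed_layers = list(
        list(W = matrix(stats::rnorm(k_in * hidden), k_in, hidden),
             activation = "relu"),
        list(W = matrix(stats::rnorm(hidden * hidden), hidden, hidden),
             activation = "relu")),
      classify_layers = list(
        list(W = matrix(stats::rnorm(hidden * hidden), hidden, hidden),
             activation = "relu")),
      Wf = matrix(stats::rnorm(hidden * n_classes), hidden, n_classes),
      bf = rep(0, n_classes))
  })
}

test_that("classify_graph is deterministic and isomorphism invariant", {
  g <- standard_graph("sbm", c(5, 5), 0.9, 0.1, seed = 2)
  g$features <- cbind(rep(1, 10), node_degrees(g))
  params <- demo_params()
  p1 <- classify_graph(g, params)
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  expect_identical(p1, classify_graph(g, params))

  # relabeled copy of the same graph gets the same probabilities
  perm <- withr::with_seed(11, sample.int(10))
  gp <- attributed_graph(cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]), 10)
  Xp <- g$features
  Xp[perm, ] <- g$features
  gp$features <- Xp
  expect_equal(classify_graph(gp, params), p1, tolerance = 1e-10)
})

test_that("pooling everything to one cluster reduces to readout on the pooled node", {
  g <- standard_graph("ring", 6)
  g$features <- cbind(rep(1, 6), node_degrees(g))
  params <- demo_params()
  params$classify_layers <- list()
  p <- classify_graph(g, params, list(method = "mpr", cover_sizes = c(1L),
                                      overlap = 0))
  # manual: embed layers then sum (S = ones column) then readout
  H <- g$features
  Nhat <- graphmapper:::normalized_adjacency(g$adjacency)
  for (ly in params$embed_layers) {
    H <- pmax(as.matrix(Nhat %*% H %*% ly$W), 0)
  }
  expect_equal(p, readout_classify(matrix(colSums(H), 1), params$Wf, params$bf),
               tolerance = 1e-12)
})

test_that("analytic gradients agree with numerical differentiation", {
  ds <- classification_dataset(4, seed = 2)
  g <- ds$graphs[[2]]
  y <- ds$graph_labels[2]
  params <- demo_params(k_in = 2, hidden = 3, seed = 9)
  plan <- graphmapper:::pooling_plan(g, list(method = "mpr",
                                             cover_sizes = c(3L, 1L),
                                             overlap = 0.25))
  cache <- graphmapper:::forward_cached(g$features, plan, params)
  grads <- graphmapper:::backward(cache, plan, params, y)
  loss_at <- function(p) {
    -log(graphmapper:::forward_cached(g$features, plan, p)$p[y + 1])
  }
  h <- 1e-6
  check_entry <- function(get, set, analytic, idx) {
    p_plus <- set(params, h, idx)
    p_minus <- set(params, -h, idx)
    num <- (loss_at(p_plus) - loss_at(p_minus)) / (2 * h)
    expect_equal(unname(analytic[idx[1], idx[2]]), num, tolerance = 1e-4)
  }
  for (idx in list(c(1, 1), c(2, 2), c(2, 3))) {
    set_w <- function(p, d, ij) {
      p$embed_layers[[1]]$W[ij[1], ij[2]] <-
        p$embed_layers[[1]]$W[ij[1], ij[2]] + d
      p
    }
    check_entry(NULL, set_w, grads$embed[[1]], idx)
    set_c <- function(p, d, ij) {
      p$classify_layers[[1]]$W[ij[1], ij[2]] <-
        p$classify_layers[[1]]$W[ij[1], ij[2]] + d
      p
    }
    check_entry(NULL, set_c, grads$classify[[1]], idx)
  }
  set_f <- function(p, d, ij) { p$Wf[ij[1], ij[2]] <- p$Wf[ij[1], ij[2]] + d; p }
  check_entry(NULL, set_f, grads$Wf, c(3, 2))
  set_b <- function(p, d, ij) { p$bf[ij[2]] <- p$bf[ij[2]] + d; p }
  check_entry(NULL, set_b, matrix(grads$bf, 1), c(1, 2))
})

test_that("training honors the epoch cap and learns the synthetic task", {
  ds <- classification_dataset(40, seed = 1)
  fit <- train_demo(ds, list(epochs = 5, seed = 0))
  expect_lte(fit$epochs_run, 5L)
  expect_lte(nrow(fit$history), 5L)
  expect_warning(train_demo(ds, list(epochs = 50, seed = 0)), "cap")

  fit2 <- train_demo(ds, list(epochs = 15, seed = 0))
  expect_gte(fit2$train_accuracy, 0.9)
})

test_that("a dataset with no signal trains to chance accuracy", {
  withr::with_seed(3, {
    graphs <- lapply(1:20, function(i) {
      g <- standard_graph("ring", 12)
      g$features <- matrix(1, 12, 2)
      g
    })
  })
  ds <- graph_dataset(graphs, rep(c(0L, 1L), 10))
  fit <- train_demo(ds, list(epochs = 10, seed = 0))
  expect_lte(fit$train_accuracy, 0.75)
  expect_gte(fit$train_accuracy, 0.25)
})
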