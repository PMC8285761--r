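# Training for the embed-pool-classify architecture.
#
# The pooling assignments (MPR) depend only on graph structure, so they are
# fixed matrices through which no gradient flows; the trainable parameters
# are the GCN weight matrices and the readout layer. Gradients are derived
# in closed form for this fixed architecture (verified against numerical
# differentiation in the test suite) and optimized with Adam.

glorot_init <- function(n_in, n_out) {
  limit <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

init_params <- function(k_in, hidden, n_classes, L_E, L_C, seed) {
  withr::with_seed(seed, {
    embed <- list()
    d <- k_in
    for (l in seq_len(L_E)) {
      embed[[l]] <- list(W = glorot_init(d, hidden), activation = "relu")
      d <- hidden
    }
    classify <- list()
    for (l in seq_len(L_C)) {
      classify[[l]] <- list(W = glorot_init(d, hidden), activation = "relu")
      d <- hidden
    }
    classifier_params(embed, classify, Wf = glorot_init(d, n_classes),
                      bf = rep(0, n_classes))
  })
}

# forward pass caching all intermediates needed for backprop
forward_cached <- function(X, plan, params) {
  cache <- list(embed = list(), classify = list())
  H <- as.matrix(X)
  N0 <- plan$norms[[1]]
  for (l in seq_along(params$embed_layers)) {
    M <- as.matrix(N0 %*% H)
    Z <- M %*% params$embed_layers[[l]]$W
    cache$embed[[l]] <- list(M = M, Z = Z)
    H <- pmax(Z, 0)
  }
  n_lev <- length(plan$assignments)
  cache$H_embed_out <- H
  if (n_lev >= 1) {
    H <- as.matrix(t(plan$assignments[[1]]) %*% H)
    Nc <- plan$norms[[2]]
    for (l in seq_along(params$classify_layers)) {
      M <- as.matrix(Nc %*% H)
      Z <- M %*% params$classify_layers[[l]]$W
      cache$classify[[l]] <- list(M = M, Z = Z)
      H <- pmax(Z, 0)
    }
    cache$H_classify_out <- H
    level <- 2L
    while (level <= n_lev) {
      H <- as.matrix(t(plan$assignments[[level]]) %*% H)
      level <- level + 1L
    }
  } else {
    cache$H_classify_out <- H
  }
  r <- colMeans(H)
  z <- as.numeric(r %*% params$Wf) + params$bf
  p <- softmax(z)
  cache$H_final <- H
  cache$r <- r
  cache$p <- p
  cache
}

# gradients of the cross-entropy loss -log p[y]
backward <- function(cache, plan, params, y) {
  p <- cache$p
  dz <- p
  dz[y + 1L] <- dz[y + 1L] - 1
  grads <- list(Wf = outer(cache$r, dz), bf = dz,
                embed = vector("list", length(params$embed_layers)),
                classify = vector("list", length(params$classify_layers)))
  dr <- as.numeric(params$Wf %*% dz)
  nH <- nrow(cache$H_final)
  dH <- matrix(rep(dr / nH, each = nH), nrow = nH)
  n_lev <- length(plan$assignments)
  if (n_lev >= 1) {
    level <- n_lev
    while (level >= 2L) {
      dH <- as.matrix(plan$assignments[[level]] %*% dH)
      level <- level - 1L
    }
    Nc <- plan$norms[[2]]
    for (l in rev(seq_along(params$classify_layers))) {
      cc <- cache$classify[[l]]
      dZ <- dH * (cc$Z > 0)
      grads$classify[[l]] <- crossprod(cc$M, dZ)
      dH <- as.matrix(Nc %*% (dZ %*% t(params$classify_layers[[l]]$W)))
    }
    dH <- as.matrix(plan$assignments[[1]] %*% dH)
  } else {
    N0 <- plan$norms[[1]]
    for (l in rev(seq_along(params$classify_layers))) {
      cc <- cache$classify[[l]]
      dZ <- dH * (cc$Z > 0)
      grads$classify[[l]] <- crossprod(cc$M, dZ)
      dH <- as.matrix(N0 %*% (dZ %*% t(params$classify_layers[[l]]$W)))
    }
  }
  N0 <- plan$norms[[1]]
  for (l in rev(seq_along(params$embed_layers))) {
    cc <- cache$embed[[l]]
    dZ <- dH * (cc$Z > 0)
    grads$embed[[l]] <- crossprod(cc$M, dZ)
    dH <- as.matrix(N0 %*% (dZ %*% t(params$embed_layers[[l]]$W)))
  }
  grads
}

flatten_params <- function(params) {
  c(lapply(params$embed_layers, `[[`, "W"),
    lapply(params$classify_layers, `[[`, "W"),
    list(params$Wf, matrix(params$bf, nrow = 1)))
}

unflatten_into <- function(params, mats) {
  LE <- length(params$embed_layers)
  LC <- length(params$classify_layers)
  for (l in seq_len(LE)) params$embed_layers[[l]]$W <- mats[[l]]
  for (l in seq_len(LC)) params$classify_layers[[l]]$W <- mats[[LE + l]]
  params$Wf <- mats[[LE + LC + 1]]
  params$bf <- as.numeric(mats[[LE + LC + 2]])
  params
}

flatten_grads <- function(grads) {
  c(grads$embed, grads$classify, list(grads$Wf, matrix(grads$bf, nrow = 1)))
}

#' Train the scaled-down graph classification demo
#'
#' Fits the embed-pool-classify architecture (GCN embedding stack, fixed
#' MPR or degree-lens DMP pooling, GCN classification stack, mean readout)
#' on a [graph_dataset()] with cross-entropy loss and Adam, using
#' hand-derived exact gradients. The pooling assignments are fixed per graph
#' and receive no gradient. Training runs for at most `epochs` epochs with
#' early stopping on validation accuracy.
#'
#' @param dataset a `graph_dataset`; all graphs need features with a common
#'   column count.
#' @param config list of options: `hidden` (width, default 16), `lr` (Adam
#'   step size, default 0.01), `epochs` (cap, default 30), `L_E` / `L_C`
#'   (layer counts, defaults 2 / 1), `seed` (default 0; drives split,
#'   shuffling and initialization), `val_frac` (default 0.2), `patience`
#'   (default 10), and the pooling block `method`, `cover_sizes`, `overlap`,
#'   `delta`.
#' @return list with `params` (best `classifier_params`), `history`
#'   (per-epoch data frame of loss and accuracies), `train_accuracy`,
#'   `val_accuracy`, `epochs_run`.
#' @export
train_demo <- function(dataset, config = list()) {
  cfg <- utils::modifyList(
    list(hidden = 16L, lr = 0.01, epochs = 30L, L_E = 2L, L_C = 1L,
         seed = 0L, val_frac = 0.2, patience = 10L,
         method = "mpr", cover_sizes = c(4L, 1L), overlap = 0.25,
         delta = NULL),
    config)
  if (cfg$epochs > 30L) {
    cfg$epochs <- 30L
    warning("epoch cap is 30; truncating")
  }
  graphs <- dataset$graphs
  labels <- dataset$graph_labels
  n <- length(graphs)
  n_classes <- length(unique(labels))
  k_in <- ncol(graphs[[1]]$features)
  pooling <- list(method = cfg$method, cover_sizes = cfg$cover_sizes,
                  overlap = cfg$overlap, delta = cfg$delta)
  plans <- lapply(graphs, pooling_plan, pooling = pooling)
  split <- withr::with_seed(cfg$seed + dataset$split_seed, {
    val <- sort(sample.int(n, max(1L, round(cfg$val_frac * n))))
    list(val = val, train = setdiff(seq_len(n), val))
  })
  params <- init_params(k_in, cfg$hidden, n_classes, cfg$L_E, cfg$L_C, cfg$seed)

  # Adam state
  mats <- flatten_params(params)
  m <- lapply(mats, function(w) w * 0)
  v <- lapply(mats, function(w) w * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0

  accuracy <- function(idx, pr) {
    preds <- vapply(idx, function(i) {
      which.max(forward_cached(graphs[[i]]$features, plans[[i]], pr)$p) - 1L
    }, 0L)
    mean(preds == labels[idx])
  }

  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_acc = numeric(0), val_acc = numeric(0))
  best <- list(val = -Inf, params = params, epoch = 0L)
  stale <- 0L
  epochs_run <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    order_idx <- withr::with_seed(cfg$seed + 1000L + epoch,
                                  sample(split$train))
    total_loss <- 0
    for (i in order_idx) {
      cache <- forward_cached(graphs[[i]]$features, plans[[i]], params)
      total_loss <- total_loss - log(max(cache$p[labels[i] + 1L], 1e-12))
      g <- backward(cache, plans[[i]], params, labels[i])
      gm <- flatten_grads(g)
      mats <- flatten_params(params)
      t_step <- t_step + 1
      for (j in seq_along(mats)) {
        m[[j]] <- b1 * m[[j]] + (1 - b1) * gm[[j]]
        v[[j]] <- b2 * v[[j]] + (1 - b2) * gm[[j]]^2
        mhat <- m[[j]] / (1 - b1^t_step)
        vhat <- v[[j]] / (1 - b2^t_step)
        mats[[j]] <- mats[[j]] - cfg$lr * mhat / (sqrt(vhat) + eps)
      }
      params <- unflatten_into(params, mats)
    }
    tr_acc <- accuracy(split$train, params)
    va_acc <- accuracy(split$val, params)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                loss = total_loss / length(split$train),
                                train_acc = tr_acc, val_acc = va_acc))
    epochs_run <- epoch
    if (va_acc > best$val) {
      best <- list(val = va_acc, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  list(params = best$params, history = history,
       train_accuracy = accuracy(split$train, best$params),
       val_accuracy = best$val, epochs_run = epochs_run)
}
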