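test_that("refined pull back splits preimages into induced components", {
  p3 <- standard_graph("path", 3)
  # nodes 1 and 3 are not adjacent: two singleton clusters
  cl <- refine_pullback(p3, list(c(1L, 3L)), "connected_components")
  expect_equal(lapply(cl, `[[`, "nodes"), list(1L, 3L))
  # trivial clustering keeps them together
  cl_t <- refine_pullback(p3, list(c(1L, 3L)), "trivial")
  expect_equal(cl_t[[1]]$nodes, c(1L, 3L))
  # empty pull back sets are dropped
  cl_e <- refine_pullback(p3, list(integer(0), c(1L, 2L)), "trivial")
  expect_length(cl_e, 1L)
  expect_equal(cl_e[[1]]$cover_index, 2L)
})

test_that("edge refinement attaches exactly the incident edges", {
  tri <- attributed_graph(rbind(c(1, 2), c(1, 3), c(2, 3)), 3)
  cl <- edge_refine(tri, refine_pullback(tri, list(1L), "trivial"))
  expect_equal(unname(tri$edges[cl[[1]]$incident_edges, , drop = FALSE]),
               rbind(c(1L, 2L), c(1L, 3L)))
  # a cluster covering V picks up all of E
  cl_all <- edge_refine(tri, refine_pullback(tri, list(1:3), "trivial"))
  expect_equal(cl_all[[1]]$incident_edges, 1:3)
  # disjoint singleton clusters on a path get disjoint incident sets
  p3 <- standard_graph("path", 3)
  cl_p <- edge_refine(p3, refine_pullback(p3, list(1L, 3L), "trivial"))
  expect_equal(cl_p[[1]]$incident_edges, 1L)
  expect_equal(cl_p[[2]]$incident_edges, 2L)
  # union of incident edges over any node cover equals E
  g <- random_graph(15, p = 0.3, seed = 4)
  lens <- pagerank_lens(g)
  memb <- hard_membership(lens, make_interval_cover(4, 0.2, 0, 1))
  cl_g <- edge_refine(g, refine_pullback(g, memb, "connected_components"))
  expect_equal(sort(unique(unlist(lapply(cl_g, `[[`, "incident_edges")))),
               seq_len(n_edges(g)))
})

test_that("nerve edges encode shared nodes (semantic) and shared edges (structural)", {
  # isolated node 3 shared by two clusters: semantic only
  g <- attributed_graph(rbind(c(1, 2)), 3)
  cl <- edge_refine(g, list(list(cover_index = 1L, cluster_index = 1L, nodes = c(1L, 3L)),
                            list(cover_index = 2L, cluster_index = 1L, nodes = c(2L, 3L))))
  s <- nerve_1skeleton(cl, g)
  # the two clusters also share edge (1,2) through endpoints 1 and 2
  expect_equal(nrow(s$edges), 1L)
  expect_true(s$edges$semantic)
  # a genuinely isolated shared node: restrict to node 3 only
  g2 <- attributed_graph(NULL, 3)
  cl2 <- edge_refine(g2, list(list(cover_index = 1L, cluster_index = 1L, nodes = c(1L, 3L)),
                              list(cover_index = 2L, cluster_index = 1L, nodes = c(2L, 3L))))
  s2 <- nerve_1skeleton(cl2, g2)
  expect_true(s2$edges$semantic)
  expect_false(s2$edges$structural)

  # path clusters {1,2} and {2,3}: share node 2 and its edges -> both flags
  p3 <- standard_graph("path", 3)
  cl3 <- edge_refine(p3, list(list(cover_index = 1L, cluster_index = 1L, nodes = c(1L, 2L)),
                              list(cover_index = 2L, cluster_index = 1L, nodes = c(2L, 3L))))
  s3 <- nerve_1skeleton(cl3, p3)
  expect_true(s3$edges$semantic && s3$edges$structural)
  expect_equal(s3$edges$shared_nodes, 1L)
  expect_equal(s3$edges$shared_edges, 2L)

  # clusters in different components never connect
  two <- attributed_graph(rbind(c(1, 2), c(3, 4)), 4)
  cl4 <- edge_refine(two, refine_pullback(two, list(c(1L, 2L), c(3L, 4L)), "trivial"))
  expect_equal(nrow(nerve_1skeleton(cl4, two)$edges), 0L)
})

test_that("single-element cover with trivial clustering collapses to one node", {
  g <- random_graph(10, p = 0.4, seed = 2)
  lens <- pagerank_lens(g)
  s <- structural_mapper(g, lens, make_interval_cover(1, 0, 0, 1), "trivial")
  expect_equal(s$n_clusters, 1L)
  expect_equal(s$size, 10L)
  expect_equal(nrow(s$edges), 0L)
})

test_that("per-node singleton covers reproduce the input graph structurally", {
  for (seed in 1:50) {
    n <- 4 + (seed %% 27)
    g <- random_graph(n, p = 0.25, seed = seed)
    # distinct lens values, one disjoint interval per node
    lens <- lens_values(seq(0, 1, length.out = n))
    eps <- 1 / (4 * n)
    centers <- seq(0, 1, length.out = n)
    cover <- interval_cover_from_elements(cbind(centers - eps, centers + eps))
    s <- structural_mapper(g, lens, cover, "connected_components")
    expect_equal(s$n_clusters, n)
    expect_equal(unlist(s$clusters), seq_len(n))
    got <- cbind(vapply(seq_len(nrow(s$edges)), function(r) s$edges$from[r], 0L),
                 s$edges$to)
    # summary edge set equals the input edge set, all structural
    expect_equal(nrow(s$edges), n_edges(g))
    if (nrow(s$edges) > 0) {
      expect_equal(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
                   unname(g$edges))
      expect_true(all(s$edges$structural))
      expect_false(any(s$edges$semantic))
    }
  }
})

test_that("Fiedler lens with a half-line cover yields the spectral bipartition", {
  check_bipartition <- function(g) {
    fl <- fiedler_lens(g)
    v <- fl$values[, 1]
    eps <- 0.5 * min(abs(v))
    cover <- interval_cover_from_elements(rbind(c(-Inf, eps), c(-eps, Inf)))
    s <- structural_mapper(g, fl, cover, "connected_components")
    expect_equal(s$n_clusters, 2L)
    expect_same_blocks(s$clusters[order(vapply(s$clusters, min, 0L))],
                       list(sort(which(v > 0)), sort(which(v < 0)))[
                         order(c(min(which(v > 0)), min(which(v < 0))))])
    expect_equal(nrow(s$edges), 1L)
    expect_true(s$edges$structural)
  }
  check_bipartition(standard_graph("barbell", c(5, 5)))
  for (g in connected_sbms(10, 6, p_in = 0.9, p_out = 0.05)) {
    check_bipartition(g)
  }
})

test_that("plain Mapper only sees semantic edges and is contained in the structural summary", {
  g <- spammer_graph(seed = 3)
  deg <- node_degrees(g)
  lens <- lens_values((deg - min(deg)) / (max(deg) - min(deg)))
  cover <- make_interval_cover(10, 0.1, 0, 1)
  plain <- plain_mapper(g, lens, cover, "connected_components")
  struct <- structural_mapper(g, lens, cover, "connected_components")
  expect_false(any(plain$edges$structural))
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(plain$edges) %in% key(struct$edges)))

  # zero-overlap cover with cc clustering: no shared nodes, plain summary edgeless
  p0 <- plain_mapper(g, lens, make_interval_cover(5, 0, 0, 1),
                     "connected_components")
  expect_equal(nrow(p0$edges), 0L)
})

test_that("summaries are deterministic and conserve nodes and edges", {
  g <- spammer_graph(seed = 8)
  lens <- pagerank_lens(g)
  cover <- make_interval_cover(8, 0.25, 0, 1)
  s1 <- structural_mapper(g, lens, cover)
  s2 <- structural_mapper(g, lens, cover)
  expect_identical(s1, s2)
  expect_equal(sort(unique(unlist(s1$clusters))), seq_len(g$n_nodes))
  expect_equal(sort(unique(unlist(s1$incident_edges))), seq_len(n_edges(g)))
  # zero-overlap + cc clustering partitions V
  s0 <- structural_mapper(g, lens, make_interval_cover(8, 0, 0, 1))
  members <- unlist(s0$clusters)
  overlap_nodes <- members[duplicated(members)]
  # only boundary lens values may duplicate; with generic PR values none do
  expect_equal(sort(members), unique(sort(members)))
})

test_that("semantic edges are monotone in overlap under trivial clustering", {
  g <- random_graph(25, p = 0.2, seed = 6, features = FALSE)
  lens <- pagerank_lens(g)
  prev <- -1L
  for (ov in c(0.05, 0.2, 0.4)) {
    s <- plain_mapper(g, lens, make_interval_cover(6, ov, 0, 1), "trivial")
    cur <- sum(s$edges$semantic)
    expect_gte(cur, prev)
    prev <- cur
  }
})
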