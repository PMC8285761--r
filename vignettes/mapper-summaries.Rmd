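---
title: "Structural Mapper summaries and soft-cluster pooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural Mapper summaries and soft-cluster pooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphmapper)
```

## The construction

`graphmapper` summarizes an attributed graph `G = (V, E)` in four steps.

1. **Lens.** A function `f : V -> R^d` (d = 1 or 2) scores every node.
   Available lenses: PageRank (`pagerank_lens`), the Fiedler vector of the
   Laplacian (`fiedler_lens`), a graph-density function
   `f(v) = sum_u exp(-D(u, v) / delta)` over hop distances (`density_lens`),
   precomputed embeddings through a pluggable reducer (`embedding_lens`),
   and the positive-class probability of a binary node classifier
   (`supervised_prob_lens`). The lens determines *what* the summary
   emphasizes; the PageRank lens groups nodes by connectivity importance,
   a classifier lens groups them by predicted class.

2. **Cover.** An ordered collection of overlapping sets covering the lens
   codomain: `n` equal-length closed intervals with overlap fraction `g`
   (`make_interval_cover`), their planar product (`make_grid_cover`), or
   `n` RBF kernels with scale `delta` (`make_rbf_cover`, soft membership
   only). More elements give finer summaries; more overlap gives more
   connected ones.

3. **Refined pull back.** Each preimage `f^-1(U_i)` is split into clusters:
   connected components of the induced subgraph (`"connected_components"`),
   or one cluster per nonempty preimage (`"trivial"`). The trivial mode is
   what pooling uses — component splitting cannot reduce the cluster count
   below the number of connected components of the input, which defeats
   coarsening on fragmented graphs.

4. **Edge refinement and nerve.** Every cluster is extended with all edges
   incident to its nodes, making the cover a cover of the whole graph, and
   the summary is the nerve 1-skeleton: one node per cluster, an edge
   whenever two clusters intersect — in nodes (*semantic*, flagged
   `semantic`) or in incident edges (*structural*, flagged `structural`).
   Without edge refinement (`plain_mapper`) only semantic edges can occur
   and structurally adjacent clusters with disjoint lens ranges appear
   disconnected; `structural_mapper`'s edge set always contains
   `plain_mapper`'s.

## Pooling as a special case

A row-stochastic assignment `S` (N x K) pools a graph via
`A' = S^T (A + I) S` and `X' = S^T X`. Expanding the product shows
`A'[i, j] != 0` exactly when some node of cluster i is adjacent (in
`A + I`) to some node of cluster j — the self-loop term makes sharing a
node sufficient. Consequently the nonzero pattern of `A'` coincides with
the nerve of the supports of the columns of `S` under trivial clustering
and edge refinement. `assignment_to_nerve()` is this statement made
executable, and the test suite checks the coincidence exactly on hundreds
of random instances and exhaustively over every labeled 4-node graph and
bipartition.

The two assignment builders:

* `mpr_assignment(g, n_clusters, overlap_g)` — PageRank lens, min-max
  rescaled to [0, 1]; interval cover of [0, 1]; each row is uniform over
  the cover elements containing the node's lens value. The operator is
  fixed (no learning) and groups nodes by connectivity importance.
* `dmp_assignment(lens, rbf_cover)` — the lens value is squashed by a
  sigmoid and softly assigned to the kernels,
  `S[i, j] = phi(z_i, x_j) / sum_j phi(z_i, x_j)`. Every entry is positive,
  but since a point on a line is close to few kernel centers, row entropy
  falls as `delta` shrinks (a property the tests verify on a fixed lens):
  low-entropy assignments arise from the topology of the cover rather than
  from a regularization loss.

## Parameters that matter

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `n` (cover size) | summary resolution / cluster budget K | task-dependent | 10 intervals for visual summaries; schedules like 20→5 or 4→1 for pooling |
| `overlap_g` | fraction of each interval shared with its neighbor | 0.1 (viz), 0.25 (pooling) | higher overlap → more semantic edges, denser summaries |
| `delta` (RBF scale) | kernel width, hence assignment softness | `1 / n^2` | larger → flatter rows (uniform at 1e6); smaller → near-one-hot |
| `damping` | PageRank teleport factor | 0.85 | the conventional value; power iteration to L1 tolerance 1e-10 |
| `scale` (density lens) | decay length in hops | none (required) | problem-specific; no universally sensible default exists |

## Numerical choices

* **Closed cover elements.** Open covers would drop nodes whose lens value
  lands exactly on a boundary; closed intervals assign them to both
  neighbors. The deviation is measure-zero and only affects ties.
* **Rescaling.** Lens values are affinely rescaled onto the cover range
  before membership so that the cover is guaranteed to cover; covers with
  unbounded endpoints (e.g. the two half-lines around zero used with the
  Fiedler lens) are applied to raw values. A constant lens maps to the
  midpoint of the range.
* **PageRank normalization.** The raw scores form a probability vector;
  the lens output is min-max rescaled so the interval cover of [0, 1] is
  fully used. Isolated nodes redistribute their mass uniformly, keeping
  the transition stochastic.
* **Fiedler sign and ties.** The eigenvector sign is fixed by making the
  lowest-id nonzero entry positive; eigenvalue multiplicity is resolved by
  the deterministic dense symmetric eigensolver. Disconnected inputs are
  rejected (lambda2 = 0 carries no bipartition information).
* **Determinism.** Pull back sets, clusters (ordered by cover element,
  then minimum member), nerve edges, DOT output and the generators under a
  fixed seed are all bit-reproducible; no global RNG state is touched.
* **Underflow.** DMP kernel rows are floored at 1e-300 and renormalized
  (with a warning) when a tiny `delta` underflows every kernel.
* **Empty cover elements** produce no nerve vertex; empty MPR columns are
  retained in `S` but dropped before pooling so no zero-feature pooled
  nodes appear; the effective K is reported.
* **Identical clusters from different cover elements** are kept as
  distinct nerve vertices — the cover is indexed, and merging would change
  the nerve.

## The classification demo

`classification_dataset(n, seed)` builds a balanced two-class set: rings
of 10-20 nodes versus two-block stochastic block models of matched size
(p_in = 0.8, p_out = 0.1), with constant and degree features. The classes
are separable from degree statistics (rings have zero degree variance), so
the task validates the architecture's plumbing rather than posing a hard
learning problem. `train_demo()` fits the embed-pool-classify model — two
GCN layers, MPR pooling with cover sizes 4 then 1 at 25% overlap, one GCN
layer on the pooled graph, mean readout — by cross-entropy and Adam for at
most 30 epochs with early stopping on a held-out fifth of the graphs.

Because the MPR assignment depends only on graph structure, it is a fixed
matrix during training and no gradient flows through pooling; the
gradients of the remaining weights are derived in closed form and verified
against central differences in the test suite. Training DMP's lens by
gradient descent would additionally require differentiating through the
kernel normalization; the package guarantees a correct deterministic
forward pass for DMP and leaves lens learning to an autodiff framework.

```{r demo, eval = FALSE}
ds  <- classification_dataset(100, seed = 0)
fit <- train_demo(ds, list(epochs = 30, seed = 0))
fit$history
```

## What the synthetic generators do and do not show

The spammer network (hubs vs small communities), SBMs, barbells and rings
exercise exactly the structures the method's claims are about: power-law-ish
hub dominance for the PageRank lens, planted bipartitions for the spectral
results, disconnected preimages for the refinement step. They do not
emulate heavy-tailed degree distributions at scale, attribute noise
correlated with structure, or the size of real molecular/social benchmark
collections. Passing tests therefore certify the construction's
correctness and its stated invariants, not downstream benchmark accuracy.
Problem sizes in the tests (graphs up to ~200 nodes, 100-graph training
sets, 200-instance property sweeps) were chosen as the smallest scales at
which every property is non-trivially exercised.

## Known limitations

* Hard membership (and hence `structural_mapper`) supports interval and
  grid covers only; RBF covers are soft by design and enter through
  `dmp_assignment`.
* Covers of lens dimension d > 2 and adaptive (equal-mass) covers are out
  of scope.
* The graph model is simple and undirected; directed input is symmetrized
  on read, parallel edges collapse with summed weight, input self-loops
  are dropped (pooling re-adds self-loops explicitly through `A + I`).
* The nerve is truncated at its 1-skeleton; higher simplices are never
  materialized.
* `train_demo` trains the fixed demo architecture only; it is not a
  general-purpose GNN trainer.
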