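---
title: "Empirical null networks for multiplex community detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical null networks for multiplex community detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multifacet)
```

## The model

A multiplex network is a family of directed graphs $G_\alpha$ on one shared,
ordered node set $V$ ($|V| = N$) with no interlayer edges. Each layer is
stored as a dense adjacency matrix $A$ with non-negative weights and a zero
diagonal; because ties are directed, $A$ is in general asymmetric. The total
weight of a layer is $L = \sum_{ij} A_{ij}$ (for a binary layer, the number
of directed edges).

Community detection maximizes the modularity of a partition $c(\cdot)$,

$$Q = \frac{1}{L} \sum_{i,j} \left( A_{ij} - P_{ij} \right)\,
      \delta(c_i, c_j),$$

summed over ordered node pairs. The matrix $B = A - P$ is the modularity
matrix. Classically $P$ is the expected adjacency of a degree-preserving
random graph; the point of this package is that $P$ can instead be an
*empirical null network* — another layer of the same multiplex, or a
complement graph of one — so that the optimizer is told which ties are
"already explained" and should not bind communities together.

### The four null constructions

* **`ng` (configuration baseline).** $P_{ij} = s_i s_j / (2S)$ with
  $s_i$ the total (in + out) strength of node $i$ and $S = \sum_i s_i = 2L$.
  On a symmetrically stored undirected graph this is exactly the textbook
  $k_i k_j / 2m$, and it satisfies $\sum_{ij} P_{ij} = L$ identically. A
  directed variant $P_{ij} = s^{out}_i s^{in}_j / L$ (Leicht–Newman) is
  available through `degree_mode = "directed"`; it also carries mass $L$.
  We default to the total-strength convention because the directed variant
  can differ noticeably on layers with strong in/out asymmetry, and the
  total-strength form is the one practitioners most often mean by
  "the" configuration null.

* **`exclusion`.** $P$ is another layer $A^{l_m}$ itself. Edges of the
  observed layer that overlap with null-layer edges are weakened in $B$;
  null-only pairs become negative. Communities avoid overlap.

* **`inclusion`.** $P$ is the *binary complement* of $A^{l_m}$: 0 where the
  null layer has an edge, 1 elsewhere (diagonal kept 0). Overlapping pairs
  are not penalized at all while non-overlapping pairs are, so communities
  collect multidimensional ties.

* **`multi`.** The observed network is the elementwise sum of several binary
  layers (weights count dimensions); the null is the *weighted complement*
  $\max(A^{null}) - A^{null}$ of the merged subset of layers being promoted,
  the maximum taken over that merged null sub-network (pairs connected in
  every promoted dimension map to 0, absent pairs to the maximum).

### Null mass and the role of $\gamma$

Layers differ in density, so a raw empirical null would enter $B$ with an
arbitrary strength. Every null is therefore rescaled to
$$\sum_{ij} P_{ij} = \gamma \, L ,$$
i.e. multiplied by $\gamma L / \sum P^{raw}$. The order of operations is a
genuine design choice (rescale then multiply by $\gamma$, rather than fold
$\gamma$ into the mass before normalizing); we normalize first so that
$\gamma = 1$ makes observed and null networks exactly equal in weight — for
two equal-density binary layers the rescaled null entries are then exactly 0
and 1 — and $\gamma$ scales null strength linearly:
$B(\gamma) = A - \gamma\,(A - B(1))$ entrywise. $\gamma = 0$ disables the
null; $\gamma > 1$ fragments modules along the null's edges. Dense nulls
(complement graphs) yield small per-pair penalties after rescaling, which is
why inclusion-mode structures react only mildly to $\gamma$, while
exclusion-mode nulls of comparable density to the observed layer reorganize
communities sharply.

A note on the diagonal: empirical nulls have a zero diagonal by
construction (layers and complements forbid self-loops), so singleton
communities contribute $Q_c = 0$ exactly. The configuration null retains its
classical diagonal $P_{ii} = s_i^2/(2S)$ — removing it would break the mass
identity $\sum P = L$ — so under `ng` an all-singletons partition has
slightly negative modularity, as in standard treatments.

## Optimization

`louvain()` is a generalized two-phase Louvain: repeated single-node moves
to the community with the largest modularity gain, then aggregation of
communities into super-nodes (summing matrix blocks, which preserves total
mass), iterated until no move improves $Q$.

Numerical and determinism choices:

* **Symmetrization.** The gain of adding node $i$ to community $C$ involves
  $B_{ij} + B_{ji}$, so the optimizer works on $B' = (B + B^\top)/2$.
  Because $Q$ sums over ordered pairs, $Q(B') = Q(B)$ for every partition
  and the optimum is unchanged for asymmetric matrices.
* **Tie-breaking.** A move needs a gain $> 10^{-12}$; among tied best
  targets the current community wins, otherwise the lowest community id.
  Together with a seeded visiting order this makes runs bit-for-bit
  reproducible given `(seed, restarts, node_order)`.
* **Restarts.** Default 20; each restart draws a fresh node-visiting
  permutation from the seed stream and the best-$Q$ result is kept.
  Empirical-null landscapes are rugged — at larger $\gamma$ the optimum
  fragments into many small modules — and restarts are cheap at these sizes
  (tens to a few hundred nodes).
* **Canonical partitions.** Community ids are renumbered $1..K$ in order of
  first appearance over nodes sorted by identifier, so outputs diff cleanly.
* **Degenerate inputs.** An all-positive off-diagonal $B$ collapses to one
  community and an all-negative one to $N$ singletons, as the modularity
  matrix dictates; both are exercised in the tests.

`exhaustive_best_partition()` enumerates all set partitions (refusing
$N > 10$; Bell(10) = 115{,}975) and is the independent oracle the optimizer
is tested against: the greedy $Q$ must never exceed the exact optimum and
matches it on at least 90% of seeded planted-two-block instances.

## Evaluation quantities

* **Local modularity** $Q_c = (1/L)\sum_{i,j \in C} B_{ij}$; local values sum
  exactly to $Q$, which the suite asserts to $10^{-9}$ on every run.
* **Overlap probability** $P(l_m \mid l_k)$: the fraction of ordered
  $l_k$-edges co-occurring with an $l_m$-edge, globally, per community, or
  pooled over all within-community pairs. A community with no internal base
  edge is reported `NA` (undefined), never 0. Reciprocal ties count as two
  trials, consistent with $L$ counting directed edges. For comparing
  detection modes we use the *pooled* within-module ratio: the per-community
  mean weights a tiny module as much as a dominant one and can move in the
  opposite direction from the edge-level quantity the modes actually
  optimize.
* **NMI** between partitions via the confusion matrix, natural logarithms,
  $0\log 0 = 0$; identical partitions give 1 (including the degenerate case
  where both are the whole node set, where the defining ratio is 0/0),
  statistically unrelated ones 0. The implementation is cross-checked
  against `igraph::compare(..., "nmi")` in the tests.
* **Layer-contribution scan.** Baseline: the configuration-model partition
  of the merged network. For every candidate layer subset (default: each
  single layer and each pair), a `multi`-mode detection is run and its NMI
  against the baseline reported. High NMI means promoting those layers
  barely changes the mesostructure — similar cohesive forces. Degenerate
  subsets (saturated merges whose complement is empty) are reported per row
  with the error message instead of aborting the scan.

## The synthetic generator

`generate_multiplex()` draws layer 1 as a directed planted-partition graph
(`p_within` inside blocks, `p_between` across) and builds each further layer
by copying each layer-1 edge with probability `overlap_within` /
`overlap_between` and adding independent noise edges at that layer's own
rates. Copying — rather than drawing layers independently — is deliberate:
the method's premise is that edge overlap concentrates inside cohesive
groups instead of spreading uniformly, and only correlated layers exercise
that regime.

The defaults (67 nodes, 6 blocks of 11–12, `p_within = 0.3`,
`p_between = 0.025`, overlap 0.8 within / 0.2 between blocks, 2 layers)
emulate the shape of a ~67-person organizational multiplex whose directed
binary layers hold roughly 300 and 440 edges with substantial, group-
concentrated overlap. Across seeds the generated layers land at roughly
290–320 and 420–450 directed edges.

What the generator does *not* emulate: heterogeneous (e.g. heavy-tailed)
degree sequences, reciprocity beyond what independent draws produce,
hierarchical or overlapping group structure, and any correlation between a
node's block and its activity level. Passing the seeded recovery and
overlap-ranking tests therefore shows the machinery is correct under
planted-block conditions, not that real organizational networks will yield
equally clean modules.

All randomness flows from a single integer seed: a splitter draws
independent sub-seeds for the generator and for each optimizer run (the
layer scan gives every row its own sub-seed), so the same master seed
reproduces every artifact bit-for-bit.

## Problem sizes and tolerances

The suite runs planted matrices of 6–10 nodes against the exhaustive oracle
(50 instances), 12–30-node multiplexes for mass/decomposition properties
(20 instances, $|\sum P - \gamma L| \le 10^{-9} L$), the deterministic
12-node toy for the mode-ranking property, and 67-node generator draws for
recovery (NMI $\ge 0.9$ against the planted blocks) and binomial moment
checks (3$\sigma$). These sizes keep the full suite under a couple of
minutes on one CPU while still covering every code path at the scale the
method targets.

## Known limitations

* Greedy Louvain gives no optimality guarantee; different visit orders can
  return different near-optimal partitions (hence seeds and restarts are
  part of the interface, and exact table-level reproduction of published
  partitions from other implementations is not promised).
* The classical resolution limit applies: modules with fewer than about
  $\sqrt{L/2}$ internal links can be absorbed regardless of the null.
  Multiresolution corrections of the configuration term are out of scope;
  $\gamma$ here scales the *empirical* null, which is related but not
  equivalent.
* Interlayer edges, temporal layers, overlapping communities and
  significance testing of $Q$ are out of scope.
* `overlap_probability()` requires binary layers; weighted layers must be
  binarized explicitly by the caller so the thresholding choice stays
  visible.
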