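# multifacet

Community detection in directed multiplex networks where the *null network*
of the modularity matrix is another empirical network layer — not a random
graph — so that detected modules deliberately avoid, or deliberately seek,
edges that overlap across layers.

## The problem

Social and organizational systems are naturally multiplex: the same actors
are connected by several kinds of directed ties (cooperation, friendship,
advice, professional esteem, ...) on one shared node set. Classical
modularity maximization compares an observed adjacency matrix **A** with the
expectation **P** of a degree-preserving random graph and groups nodes where
connections exceed that random expectation:

    Q = (1/L) * sum_ij (A_ij - P_ij) * delta(c_i, c_j),      L = sum_ij A_ij

`multifacet` keeps this machinery but replaces **P** with empirical
information from the other layers, rescaled so that `sum(P) = gamma * L`
(at `gamma = 1` the observed and null networks carry equal total weight):

| mode        | observed **A**                  | null **P** (before rescaling)         | communities found |
|-------------|---------------------------------|----------------------------------------|-------------------|
| `ng`        | one layer (or a weighted merge) | configuration model `k_i k_j / 2m`     | classical baseline |
| `exclusion` | layer `l_k`                     | layer `l_m` itself                     | avoid `l_m` edges inside modules |
| `inclusion` | layer `l_k`                     | complement graph of `l_m` (0 if `l_m` edge, 1 otherwise) | favour pairs also tied in `l_m` |
| `multi`     | weighted merge of layers        | weighted complement `max(A_null) - A_null` of a merged layer subset | promote chosen layers inside modules |

The resulting modularity matrix `B = A - P` (real, possibly asymmetric and
negative) is optimized with a generalized Louvain procedure, and the
communities are characterized by their local modularity `Q_c` and by the
within-module edge-overlap probability `P(l_m | l_k)` — the fraction of
observed-layer edges inside a module that co-occur with a null-layer edge on
the same ordered node pair. Partition similarity is measured with
confusion-matrix NMI.

Intended users: network scientists and organizational researchers analyzing
directed multiplex data who want module structure conditioned on — rather
than blind to — edge overlap between layers.

## Worked example

The packaged 12-node toy (`fig1_toy()`) has a "black" layer with three
4-cliques (two of them bridged) and a "red" layer duplicating the black
edges of the bridged pair only:

```r
library(multifacet)
M <- fig1_toy()

fit <- multifacet(M, mode = "exclusion", observed = "black", null = "red",
                  seed = 1)
print(fit)
#> Mode: exclusion   observed: black   null: red   gamma = 1
#> N = 12 nodes, K = 9 communities, Q = 0.2500 (louvain, 20 restarts, seed 1)
#> Community sizes: 4 1 1 1 1 1 1 1 1

summary(fit, base = "black", cond = "red")
#> Mode exclusion (gamma = 1): K = 9 communities, global Q = 0.2500
#>  community n_members  Q_c overlap_prob
#>          1         1 0.00           NA
#>        ...
#>          9         4 0.25            0
```

Every red-overlapped edge is driven out of the modules: only the clean
4-clique survives as a community (`Q_c = 0.25`, overlap 0), the
red-overlapped actors end up as singletons (`Q_c = 0`, overlap undefined).
The same toy under the other nulls:

```r
summary(multifacet(M, "ng", observed = "black", seed = 1),
        base = "black", cond = "red")
#> K = 3 communities, global Q = 0.4062   (three cliques; overlap 1, 1, 0)
summary(multifacet(M, "inclusion", observed = "black", null = "red", seed = 1),
        base = "black", cond = "red")
#> K = 2 communities, global Q = 0.6667   (red-overlapped pair glued; overlap 1, 0)
```

so the pooled within-module overlap ranks exclusion (0) < configuration
baseline (0.67) < inclusion (0.75): the null network is a dial for how much
multidimensionality communities should contain.

A command-line interface is installed alongside the package
(`exec/multifacet`), with subcommands `detect`, `scan-layers`, `compare`,
`summarize` and `simulate` over a layered CSV edge-list format
(`source,target,layer,weight`).

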