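# Null-network construction: configuration model, rescaling, and the
# exclusion / inclusion / merged-multilayer modularity matrices.

test_that("configuration null reproduces the classical formula and mass L", {
  # undirected 4-cycle stored symmetrically: L = 8, textbook k_i k_j / 2m
  # gives P_ij = 2*2/8 = 0.5 for every pair
  w <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; w[i, j] <- 1; w[j, i] <- 1 }
  bm <- configuration_null(mpx_layer(w, "cycle"))
  expect_equal(bm$L, 8)
  expect_true(all(abs(bm$P - 0.5) < 1e-12))
  expect_equal(bm$B, w - 0.5, ignore_attr = TRUE)

  # sum(P) = L in both degree conventions, also on directed layers
  set.seed(21)
  for (r in 1:5) {
    l <- mpx_layer(rand_binary_adj(10, 0.3))
    expect_equal(sum(configuration_null(l, "total")$P), total_weight(l))
    expect_equal(sum(configuration_null(l, "directed")$P), total_weight(l))
  }
  expect_error(configuration_null(mpx_layer(matrix(0, 3, 3))), "zero total")
})

test_that("a single undirected edge is grouped, not split, under the NG null", {
  w <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("u", "v"), c("u", "v")))
  bm <- configuration_null(mpx_layer(w))
  together <- as_partition(c(u = 1, v = 1))
  apart <- as_partition(c(u = 1, v = 2))
  expect_gt(modularity_score(bm, together), modularity_score(bm, apart))
  fit <- louvain(bm, seed = 1)
  expect_equal(fit$K, 1)
})

test_that("configuration null matches igraph modularity on undirected graphs", {
  skip_if_not_installed("igraph")
  set.seed(5)
  g <- igraph::sample_gnp(20, 0.25)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  bm <- configuration_null(mpx_layer(A))
  memb <- sample(1:4, 20, replace = TRUE)
  expect_equal(modularity_score(bm, as_partition(memb, nodes = bm$nodes)),
               igraph::modularity(g, memb))
})

test_that("normalize_null rescales the raw null to gamma * L", {
  set.seed(31)
  P_raw <- rand_binary_adj(8, 0.4)
  L <- 17.3
  for (g in c(0.5, 1, 2))
    expect_equal(sum(normalize_null(P_raw, L, g)), g * L)
  # already mass-matched null is untouched at gamma 1
  Pm <- P_raw * (L / sum(P_raw))
  expect_equal(normalize_null(Pm, L, 1), Pm)
  # gamma 0 disables the null
  expect_true(all(normalize_null(P_raw, L, 0) == 0))
  # a 440-edge null against a 305-edge observed layer: each unit edge
  # scaled to 305/440
  Pn <- matrix(0, 30, 30)
  off <- which(row(Pn) != col(Pn))
  Pn[off[seq_len(440)]] <- 1
  stopifnot(sum(Pn) == 440)
  scaled <- normalize_null(Pn, 305, 1)
  expect_equal(sort(unique(as.vector(scaled))), c(0, 305 / 440))
  expect_error(normalize_null(matrix(0, 3, 3), 10, 1), "empty")
  expect_error(normalize_null(P_raw, 10, -1), "non-negative")
})

test_that("exclusion matrix realizes the connectivity-surplus cases", {
  # equal-density binary layers at gamma 1: scale factor is exactly 1, so
  # B is 0 on overlapped pairs, 1 on observed-only, -1 on null-only
  nodes <- letters[1:4]
  a <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  p <- a
  a["a", "b"] <- 1; a["b", "c"] <- 1          # observed
  p["a", "b"] <- 1; p["c", "d"] <- 1          # null, same density
  M <- multiplex(list(obs = a, nul = p))
  bm <- exclusion_matrix(M, "obs", "nul", gamma = 1)
  expect_equal(bm$B["a", "b"], 0)   # overlap: no connectivity surplus
  expect_equal(bm$B["b", "c"], 1)   # observed only: surplus
  expect_equal(bm$B["c", "d"], -1)  # null only: deficit
  expect_equal(bm$B["d", "a"], 0)   # neither: irrelevant

  # gamma 0 leaves the observed adjacency untouched
  bm0 <- exclusion_matrix(M, "obs", "nul", gamma = 0)
  expect_equal(bm0$B, a, ignore_attr = TRUE)

  # random 6-node two-layer fixture vs elementwise oracle A - gamma*s*A_null
  set.seed(41)
  M2 <- rand_multiplex(6)
  g <- 1.5
  bm2 <- exclusion_matrix(M2, "l1", "l2", gamma = g)
  w1 <- get_layer(M2, "l1")$weights
  w2 <- get_layer(M2, "l2")$weights
  s <- sum(w1) / sum(w2)
  for (i in 1:6) for (j in 1:6)
    expect_equal(bm2$B[i, j], w1[i, j] - g * s * w2[i, j])

  expect_error(exclusion_matrix(M, "obs", "obs"), "must differ")
})

test_that("inclusion matrix penalizes only pairs missing from the null layer", {
  nodes <- letters[1:4]
  a <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  n <- a
  a["a", "b"] <- 1; a["b", "c"] <- 1
  n["a", "b"] <- 1; n["a", "c"] <- 1
  M <- multiplex(list(obs = a, nul = n))
  bm <- inclusion_matrix(M, "obs", "nul", gamma = 1)
  scale <- sum(a) / (12 - sum(n))             # L_obs / |complement|
  # connected in both layers: complement 0, no penalty
  expect_equal(bm$B["a", "b"], a["a", "b"])
  # connected in observed only: penalized by gamma * scale
  expect_equal(bm$B["b", "c"], 1 - scale)
  # elementwise oracle on a random fixture with a dense null layer
  set.seed(51)
  M2 <- rand_multiplex(7, p1 = 0.4, p2 = 0.8)
  bm2 <- inclusion_matrix(M2, "l1", "l2", gamma = 2)
  w1 <- get_layer(M2, "l1")$weights
  w2 <- get_layer(M2, "l2")$weights
  comp <- 1 - w2; diag(comp) <- 0
  sc <- sum(w1) / sum(comp)
  for (i in 1:7) for (j in 1:7)
    expect_equal(bm2$B[i, j], w1[i, j] - 2 * sc * comp[i, j])

  Mw <- multiplex(list(obs = a, nul = 2 * n))
  expect_error(inclusion_matrix(Mw, "obs", "nul"), "multi_matrix")
})

test_that("multi matrix merges, complements with max-minus-weight, rescales", {
  set.seed(61)
  layers <- list(l1 = rand_binary_adj(8, 0.4),
                 l2 = rand_binary_adj(8, 0.4),
                 l3 = rand_binary_adj(8, 0.4))
  M <- multiplex(layers)
  g <- 1
  bm <- multi_matrix(M, c("l1", "l2", "l3"), c("l1", "l2"), gamma = g)
  A <- Reduce(`+`, lapply(M$layers, `[[`, "weights"))
  nul <- get_layer(M, "l1")$weights + get_layer(M, "l2")$weights
  comp <- max(nul) - nul; diag(comp) <- 0
  s <- sum(A) / sum(comp)
  for (i in 1:8) for (j in 1:8)
    expect_equal(bm$B[i, j], A[i, j] - g * s * comp[i, j])

  # single binary null layer inside a merge: identical to the inclusion
  # construction applied to the merged observed network
  Mplus <- multiplex(c(layers, list(merged = A)))
  bm_multi <- multi_matrix(M, c("l1", "l2", "l3"), "l1")
  bm_incl <- inclusion_matrix(Mplus, "merged", "l1")
  expect_equal(bm_multi$B, bm_incl$B, ignore_attr = TRUE)

  # saturated null merge (every off-diagonal weight at the maximum) is
  # surfaced as an empty-null error
  full <- matrix(1, 5, 5); diag(full) <- 0
  Msat <- multiplex(list(l1 = full, l2 = full))
  expect_error(multi_matrix(Msat, c("l1", "l2"), c("l1", "l2")), "empty null")
  expect_error(multi_matrix(M, c("l1"), c("l2")), "subset")
  expect_error(multi_matrix(M, character(), character()), "at least one")
})

test_that("null mass is gamma * L in every mode and B is affine in gamma", {
  set.seed(71)
  for (r in 1:5) {
    M <- rand_multiplex(9, 0.35, 0.45)
    L1 <- total_weight(get_layer(M, "l1"))
    builders <- list(
      ng = function(g) configuration_null(get_layer(M, "l1")),
      exclusion = function(g) exclusion_matrix(M, "l1", "l2", gamma = g),
      inclusion = function(g) inclusion_matrix(M, "l1", "l2", gamma = g),
      multi = function(g) multi_matrix(M, c("l1", "l2"), "l2", gamma = g))
    for (mode in names(builders)) {
      gammas <- if (mode == "ng") 1 else c(0.5, 1, 2)
      for (g in gammas) {
        bm <- builders[[mode]](g)
        expect_lt(abs(sum(bm$P) - g * bm$L), 1e-9 * bm$L)
      }
      if (mode != "ng") {
        b1 <- builders[[mode]](1)
        A <- b1$B + b1$P
        for (g in c(0, 0.5, 2)) {
          bg <- builders[[mode]](g)
          expect_equal(bg$B, A - g * (A - b1$B), tolerance = 1e-12)
        }
      }
    }
  }
})
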