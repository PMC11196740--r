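# Independent oracles and fixture builders used across the suite.

# brute-force modularity: explicit double loop over ordered pairs (incl. i=j)
brute_modularity <- function(B, a, L) {
  n <- nrow(B)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (a[i] == a[j]) s <- s + B[i, j]
  s / L
}

# brute-force local modularity of one community: restricted double loop
brute_local_modularity <- function(B, a, k, L) {
  idx <- which(a == k)
  s <- 0
  for (i in idx) for (j in idx) s <- s + B[i, j]
  s / L
}

# random directed binary adjacency matrix (zero diagonal, named nodes)
rand_binary_adj <- function(n, p) {
  nodes <- sprintf("v%02d", seq_len(n))
  w <- matrix(rbinom(n * n, 1, p), n, n, dimnames = list(nodes, nodes))
  diag(w) <- 0
  w
}

# random two-layer binary multiplex on n nodes
rand_multiplex <- function(n, p1 = 0.4, p2 = 0.4) {
  multiplex(list(l1 = rand_binary_adj(n, p1), l2 = rand_binary_adj(n, p2)))
}

# wrap a raw matrix as a modularity matrix (for optimizer tests on arbitrary B)
raw_bm <- function(B, L = 1) {
  if (is.null(rownames(B))) {
    nodes <- sprintf("v%02d", seq_len(nrow(B)))
    dimnames(B) <- list(nodes, nodes)
  }
  multifacet:::new_modularity_matrix(B = B, P = 0 * B, L = L, gamma = 1,
                                     mode = "exclusion",
                                     observed_layers = "obs",
                                     null_layers = "null")
}

# planted two-block matrix: positive within blocks, negative across, noise sd
planted_block_B <- function(n, sd = 0.25, strength = 0.4) {
  blk <- rep(1:2, times = c(ceiling(n / 2), floor(n / 2)))
  B <- matrix(rnorm(n * n, ifelse(outer(blk, blk, "=="), strength, -strength),
                    sd), n, n)
  diag(B) <- 0
  nodes <- sprintf("v%02d", seq_len(n))
  dimnames(B) <- list(nodes, nodes)
  list(B = B, truth = setNames(blk, nodes))
}
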