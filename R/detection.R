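# Modularity of a partition for an arbitrary modularity matrix, and its
# optimization by a generalized two-phase (local moving + aggregation) Louvain
# procedure that accepts any real matrix B, not just A minus a random-graph
# expectation.

#' Modularity of a partition
#'
#' \eqn{Q = (1/L) \sum_{ij} B_{ij} \delta(c_i, c_j)}, summed over ordered node
#' pairs (including \eqn{i = j}; the diagonal of \eqn{B} is zero for the
#' empirical-null modes and \eqn{-P_{ii}} for the configuration null).
#'
#' @param Bm a \code{modularity_matrix}.
#' @param part a partition covering all nodes of \code{Bm} (named community
#'   vector; see \code{\link{as_partition}}).
#' @return The modularity value \eqn{Q}.
#' @export
modularity_score <- function(Bm, part) {
  stopifnot(inherits(Bm, "modularity_matrix"))
  a <- check_partition(part, Bm$nodes)
  sum(Bm$B[outer(a, a, "==")]) / Bm$L
}

#' Local modularity of one community
#'
#' The additive contribution of community \code{community} to the global
#' modularity: \eqn{Q_c = (1/L) \sum_{i,j \in C} B_{ij}}.  Local modularities
#' sum to \eqn{Q} over the communities of a partition.
#'
#' @inheritParams modularity_score
#' @param community a community id present in \code{part}.
#' @return The local modularity \eqn{Q_c}.
#' @export
local_modularity <- function(Bm, part, community) {
  stopifnot(inherits(Bm, "modularity_matrix"))
  a <- check_partition(part, Bm$nodes)
  if (!community %in% a)
    stopf("community '%s' is not present in the partition", community)
  idx <- which(a == community)
  sum(Bm$B[idx, idx, drop = FALSE]) / Bm$L
}

# one full Louvain run (local moving + aggregation to convergence) on the
# symmetrized matrix; returns the membership of the original nodes.
louvain_once <- function(Bp, shuffle) {
  n0 <- nrow(Bp)
  assign_orig <- seq_len(n0)
  M <- Bp
  tol <- 1e-12
  repeat {
    n <- nrow(M)
    a <- seq_len(n)
    visit <- if (shuffle) sample.int(n) else seq_len(n)
    repeat {
      moved <- FALSE
      for (i in visit) {
        w <- 2 * M[i, ]
        w[i] <- 0
        g <- rowsum(w, a)                   # gain of sitting in each community
        ids <- as.integer(rownames(g))
        gcur <- g[match(a[i], ids), 1]
        gmax <- max(g[, 1])
        if (gmax > gcur + tol) {            # ties keep the current community
          cand <- ids[g[, 1] >= gmax - tol]
          target <- min(cand)               # then lowest community id
          if (target != a[i]) {
            a[i] <- target
            moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
    a <- match(a, unique(a))                # contiguous ids 1..K
    K <- max(a)
    assign_orig <- a[assign_orig]
    if (K == n) break                       # no aggregation possible
    M <- rowsum(t(rowsum(M, a)), a)         # community-by-community sums
  }
  assign_orig
}

#' Maximize modularity with a generalized Louvain procedure
#'
#' Greedy two-phase Louvain (local node moving, then aggregation of
#' communities into super-nodes) operating on the symmetrized matrix
#' \eqn{B' = (B + B^T)/2}.  Because \eqn{Q} sums over ordered pairs, it is
#' invariant under this symmetrization, so the optimum is unchanged for
#' asymmetric (directed) matrices.  The best result over \code{restarts}
#' random node-visiting orders is returned; runs are deterministic given
#' \code{(seed, restarts, node_order)}.
#'
#' @param Bm a \code{modularity_matrix}.
#' @param seed integer seed controlling all node-order shuffles.
#' @param restarts number of independent restarts (>= 1); each restart draws a
#'   fresh visiting order from the seed stream.
#' @param node_order \code{"shuffled"} (default) or \code{"sorted"} (fixed
#'   index order; restarts are then identical).
#' @return A \code{multifacet} detection result: list with \code{partition}
#'   (canonical named community vector), \code{Q}, \code{K},
#'   \code{restarts_used}, \code{seed}, \code{trace} (Q of every restart) and
#'   \code{matrix} (the input \code{Bm}).
#' @seealso \code{\link{exhaustive_best_partition}} for an exact oracle on
#'   tiny networks, \code{\link{multifacet}} for the high-level interface.
#' @export
louvain <- function(Bm, seed = 1L, restarts = 20L,
                    node_order = c("shuffled", "sorted")) {
  stopifnot(inherits(Bm, "modularity_matrix"))
  node_order <- match.arg(node_order)
  if (restarts < 1) stopf("'restarts' must be >= 1")
  Bp <- (Bm$B + t(Bm$B)) / 2
  best <- NULL
  trace <- numeric(restarts)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      memb <- louvain_once(Bp, shuffle = node_order == "shuffled")
      Q <- sum(Bp[outer(memb, memb, "==")]) / Bm$L
      trace[r] <- Q
      if (is.null(best) || Q > best$Q + 1e-12)
        best <- list(memb = memb, Q = Q)
    }
  })
  part <- as_partition(best$memb, nodes = Bm$nodes)
  new_multifacet(partition = part, Q = modularity_score(Bm, part),
                 matrix = Bm, method = "louvain", seed = seed,
                 restarts_used = restarts, trace = trace)
}

# enumerate restricted-growth strings (canonical set partitions) of length n,
# calling fn(a) for each
enumerate_partitions <- function(n, fn) {
  a <- integer(n)
  recurse <- function(pos, mx) {
    if (pos > n) {
      fn(a)
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) {
      a[pos] <<- v
      recurse(pos + 1L, max(mx, v))
    }
  }
  recurse(1L, 0L)
}

#' Exact maximum-modularity partition by exhaustive enumeration
#'
#' Enumerates every set partition of the node set (feasible for N <= 10) and
#' returns the one with maximal modularity.  Ties are broken toward fewer
#' communities, then toward the lexicographically smallest canonical
#' assignment.  Intended as an independent oracle for testing the greedy
#' optimizer, not for analysis.
#'
#' @param Bm a \code{modularity_matrix} with at most 10 nodes.
#' @return A \code{multifacet} detection result (see \code{\link{louvain}}).
#' @export
exhaustive_best_partition <- function(Bm) {
  stopifnot(inherits(Bm, "modularity_matrix"))
  n <- length(Bm$nodes)
  if (n > 10)
    stopf("exhaustive enumeration refused for N = %d > 10 nodes", n)
  B <- Bm$B
  L <- Bm$L
  tol <- 1e-12
  best_Q <- -Inf
  best_K <- Inf
  best_a <- NULL
  enumerate_partitions(n, function(a) {
    Q <- sum(B[outer(a, a, "==")]) / L
    K <- max(a)
    if (Q > best_Q + tol ||
        (Q >= best_Q - tol && K < best_K)) {
      best_Q <<- Q
      best_K <<- K
      best_a <<- a
    }
  })
  part <- as_partition(best_a, nodes = Bm$nodes)
  new_multifacet(partition = part, Q = modularity_score(Bm, part),
                 matrix = Bm, method = "exhaustive", seed = NA_integer_,
                 restarts_used = NA_integer_, trace = NULL)
}
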