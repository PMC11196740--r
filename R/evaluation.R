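# Quantifying community structures: normalized mutual information between
# partitions, within-module edge-overlap probabilities, per-module summary
# tables, and the layer-contribution scan against the configuration baseline.

#' Normalized mutual information between two partitions
#'
#' Confusion-matrix NMI: with \eqn{N_{ij}} the number of nodes in community
#' \eqn{i} of \code{x} and community \eqn{j} of \code{y},
#' \deqn{NMI = \frac{-2 \sum_{ij} N_{ij} \log(N_{ij} N / N_{i.} N_{.j})}
#'                  {\sum_i N_{i.} \log(N_{i.}/N) +
#'                   \sum_j N_{.j} \log(N_{.j}/N)}}
#' using natural logarithms (the ratio is base-invariant) and the convention
#' \eqn{0 \log 0 = 0}.  Identical partitions give 1, statistically unrelated
#' ones 0.  When both partitions are the single whole-set community the ratio
#' is 0/0 and 1 is returned (the partitions are identical).
#'
#' @param x,y partitions of the same node set (named community vectors, or
#'   unnamed vectors of equal length compared positionally).
#' @return NMI value in \eqn{[0, 1]}.
#' @export
nmi <- function(x, y) {
  if (is.null(names(x)) != is.null(names(y)))
    stopf("both partitions must be named, or both unnamed")
  if (is.null(names(x))) {
    if (length(x) != length(y))
      stopf("partitions cover different numbers of nodes (%d vs %d)",
            length(x), length(y))
    nodes <- seq_along(x)
    x <- as_partition(x, nodes = nodes)
    y <- as_partition(y, nodes = nodes)
  } else {
    x <- as_partition(x)
    y <- as_partition(y)
    if (!identical(names(x), names(y)))
      stopf("partitions cover different node sets")
  }
  N <- length(x)
  tab <- table(x, y)
  Ni <- rowSums(tab)
  Nj <- colSums(tab)
  ratio <- tab * N / outer(Ni, Nj)
  terms <- tab * log(ratio)
  terms[tab == 0] <- 0                       # 0 log 0 = 0
  num <- -2 * sum(terms)
  den <- sum(Ni * log(Ni / N)) + sum(Nj * log(Nj / N))
  if (den == 0) return(1)                    # both are the whole-set community
  num / den
}

#' Edge-overlap probability between two binary layers
#'
#' The probability that a directed edge of the \code{base} layer co-occurs
#' with an edge of the \code{cond} layer on the same ordered node pair:
#' \eqn{P(cond | base) = |base \cap cond| / |base|}, counted over ordered
#' pairs (a reciprocal pair contributes two trials).
#'
#' With a partition, the ratio is restricted to pairs inside the same
#' community and reported per community; communities with no internal base
#' edge yield \code{NA} (undefined, not zero).  With
#' \code{per_community = FALSE} the within-module pairs of all communities are
#' pooled into a single ratio, the natural aggregate for comparing detection
#' modes.
#'
#' @param M a \code{multiplex} network.
#' @param base name of the binary layer whose edges are the trials.
#' @param cond name of the binary layer whose co-occurrence is measured.
#' @param part optional partition of the nodes of \code{M}.
#' @param per_community with a partition, report one ratio per community
#'   (default) or one pooled within-module ratio.
#' @return A single probability (no partition, or pooled), or a named numeric
#'   vector with one entry per community id.
#' @export
overlap_probability <- function(M, base, cond, part = NULL,
                                per_community = TRUE) {
  stopifnot(inherits(M, "multiplex"))
  A <- get_layer(M, base)$weights
  C <- get_layer(M, cond)$weights
  if (!is_binary_matrix(A) || !is_binary_matrix(C))
    stopf("overlap probability needs binary layers; binarize explicitly first")
  ratio <- function(mask) {
    nb <- sum(A == 1 & mask)
    if (nb == 0) NA_real_ else sum(A == 1 & C == 1 & mask) / nb
  }
  if (is.null(part))
    return(ratio(TRUE))
  a <- check_partition(part, M$nodes)
  same <- outer(a, a, "==")
  if (!per_community)
    return(ratio(same))
  ids <- sort(unique(a))
  out <- vapply(ids, function(k) ratio(outer(a == k, a == k, "&")),
                numeric(1))
  names(out) <- ids
  out
}

#' Per-module summary table
#'
#' One row per community of a partition: community id, number of members,
#' local modularity \eqn{Q_c}, and (when \code{M}, \code{base} and
#' \code{cond} are supplied) the within-module edge-overlap probability.
#' Rows are sorted by community id; local modularities sum to the global Q.
#'
#' @param Bm a \code{modularity_matrix}.
#' @param part a partition of the nodes of \code{Bm}.
#' @param M optional \code{multiplex} network for the overlap column.
#' @param base,cond optional binary layer names (see
#'   \code{\link{overlap_probability}}).
#' @return A data frame with columns \code{community}, \code{n_members},
#'   \code{Q_c}, \code{overlap_prob} (\code{NA} where undefined).
#' @export
module_summary <- function(Bm, part, M = NULL, base = NULL, cond = NULL) {
  stopifnot(inherits(Bm, "modularity_matrix"))
  a <- check_partition(part, Bm$nodes)
  ids <- sort(unique(a))
  qc <- vapply(ids, function(k) local_modularity(Bm, a, k), numeric(1))
  ov <- rep(NA_real_, length(ids))
  if (!is.null(base) && !is.null(cond)) {
    if (is.null(M))
      stopf("a multiplex network 'M' is needed for the overlap column")
    ovk <- overlap_probability(M, base, cond, part = a)
    ov <- unname(ovk[as.character(ids)])
  }
  data.frame(community = ids,
             n_members = as.integer(table(a)[as.character(ids)]),
             Q_c = qc,
             overlap_prob = ov,
             row.names = NULL)
}

#' Scan the contribution of each layer to the community structure
#'
#' Baseline: the configuration-model (NG) community structure of the merged
#' \code{observed} network.  For every candidate subset of layers, detect
#' communities with the merged-multilayer mode promoting that subset
#' (\code{\link{multi_matrix}}) and report the modularity and the NMI between
#' the resulting partition and the baseline.  High NMI means promoting those
#' layers barely changes the mesostructure, i.e. similar cohesive forces.
#'
#' @param M a \code{multiplex} network.
#' @param observed layer names forming the merged observed network (default:
#'   all layers).
#' @param candidate_nulls list of layer-name subsets to promote; default every
#'   single layer and every pair of \code{observed}.
#' @param gamma null-strength multiplier (default 1).
#' @param seed master seed; per-row optimizer seeds are derived from it.
#' @param restarts Louvain restarts per detection.
#' @param degree_mode degree convention for the baseline configuration null.
#' @return A data frame with one row per candidate subset: columns
#'   \code{promoted_layers}, \code{Q}, \code{nmi}, \code{note} (\code{NA}, or
#'   the error message for a degenerate subset whose Q and NMI are \code{NA}).
#'   The baseline fit and partition are attached as attributes
#'   \code{"baseline_Q"} and \code{"baseline_partition"}.
#' @export
layer_contribution_scan <- function(M, observed = layer_names(M),
                                    candidate_nulls = NULL,
                                    gamma = 1, seed = 1L, restarts = 20L,
                                    degree_mode = c("total", "directed")) {
  stopifnot(inherits(M, "multiplex"))
  degree_mode <- match.arg(degree_mode)
  if (is.null(candidate_nulls)) {
    singles <- as.list(observed)
    pairs <- if (length(observed) >= 2)
      utils::combn(observed, 2, simplify = FALSE) else list()
    candidate_nulls <- c(singles, pairs)
  }
  if (length(candidate_nulls) == 0)
    stopf("'candidate_nulls' must contain at least one layer subset")
  seeds <- split_seed(seed, length(candidate_nulls) + 1L)
  base_fit <- louvain(configuration_null(merge_layers(M, observed),
                                         degree_mode = degree_mode),
                      seed = seeds[1], restarts = restarts)
  rows <- lapply(seq_along(candidate_nulls), function(i) {
    subset <- candidate_nulls[[i]]
    res <- tryCatch({
      fit <- louvain(multi_matrix(M, observed, subset, gamma = gamma),
                     seed = seeds[i + 1L], restarts = restarts)
      list(Q = fit$Q, nmi = nmi(fit$partition, base_fit$partition),
           note = NA_character_)
    }, error = function(e) list(Q = NA_real_, nmi = NA_real_,
                                note = conditionMessage(e)))
    data.frame(promoted_layers = paste(subset, collapse = "+"),
               Q = res$Q, nmi = res$nmi, note = res$note,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_Q") <- base_fit$Q
  attr(out, "baseline_partition") <- base_fit$partition
  out
}
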