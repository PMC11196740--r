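# Construction of modularity matrices B = A - P, where the null network P is
# either the configuration-model expectation or an empirical layer (or its
# complement graph), rescaled so that at gamma = 1 the null carries the same
# total weight L as the observed network.

new_modularity_matrix <- function(B, P, L, gamma, mode,
                                  observed_layers, null_layers) {
  structure(list(B = B, P = P, L = L, gamma = gamma, mode = mode,
                 observed_layers = observed_layers,
                 null_layers = null_layers,
                 nodes = rownames(B)),
            class = "modularity_matrix")
}

#' @export
print.modularity_matrix <- function(x, ...) {
  cat(sprintf(
    "<modularity_matrix>  mode = %s, %d nodes, L = %g, gamma = %g\n",
    x$mode, length(x$nodes), x$L, x$gamma))
  cat(sprintf("  observed: %s\n", paste(x$observed_layers, collapse = "+")))
  if (length(x$null_layers))
    cat(sprintf("  null:     %s\n", paste(x$null_layers, collapse = "+")))
  invisible(x)
}

#' Rescale a raw null network to a target total weight
#'
#' Multiplies a non-negative null matrix by \code{gamma * L / sum(P_raw)}, so
#' that the rescaled null sums to \code{gamma * L}.  At \code{gamma = 1} the
#' observed and null networks then carry the same total weight and a density
#' difference between layers cannot dominate the modularity matrix.
#'
#' @param P_raw square non-negative numeric matrix with positive total.
#' @param L total weight of the observed network (> 0).
#' @param gamma null-strength multiplier (>= 0); \code{gamma = 0} disables
#'   the null entirely.
#' @return Rescaled matrix summing to \code{gamma * L}.
#' @export
normalize_null <- function(P_raw, L, gamma = 1) {
  P_raw <- as.matrix(P_raw)
  s <- sum(P_raw)
  if (!is.finite(s) || s <= 0)
    stopf("null network is empty (sum of raw null weights is %g)", s)
  if (!is.finite(L) || L <= 0) stopf("observed total weight L must be > 0")
  if (gamma < 0) stopf("gamma must be non-negative")
  gamma * (L / s) * P_raw
}

#' Configuration-model (Newman-Girvan) modularity matrix
#'
#' The classical random null: \eqn{P_{ij}} is the expected weight between
#' \eqn{i} and \eqn{j} in a random graph preserving the node
#' degrees/strengths of the layer.  Two conventions are available:
#' \describe{
#'   \item{\code{"total"}}{\eqn{P_{ij} = s_i s_j / (2S)} with \eqn{s_i} the
#'     total (in + out) strength and \eqn{S = \sum_i s_i = 2L}.  On a
#'     symmetrically stored undirected graph this is exactly the textbook
#'     \eqn{k_i k_j / 2m}.}
#'   \item{\code{"directed"}}{\eqn{P_{ij} = s^{out}_i s^{in}_j / L}, the
#'     Leicht-Newman directed null.}
#' }
#' Both satisfy \eqn{\sum_{ij} P_{ij} = L} exactly, so the null carries the
#' same total weight as the observed layer.
#'
#' @param layer an \code{mpx_layer} with positive total weight.
#' @param degree_mode \code{"total"} or \code{"directed"} (see above).
#' @return A \code{modularity_matrix} with \code{mode = "ng"} and
#'   \code{gamma = 1}.
#' @export
configuration_null <- function(layer, degree_mode = c("total", "directed")) {
  stopifnot(inherits(layer, "mpx_layer"))
  degree_mode <- match.arg(degree_mode)
  A <- layer$weights
  L <- sum(A)
  if (L <= 0) stopf("layer '%s' has zero total weight", layer$name)
  if (degree_mode == "total") {
    s <- rowSums(A) + colSums(A)       # in + out strength, sums to 2L
    P <- outer(s, s) / (2 * sum(s))
  } else {
    P <- outer(rowSums(A), colSums(A)) / L
  }
  dimnames(P) <- dimnames(A)
  new_modularity_matrix(B = A - P, P = P, L = L, gamma = 1, mode = "ng",
                        observed_layers = layer$name, null_layers = character())
}

#' Exclusion-mode modularity matrix: discourage edge overlap
#'
#' Observed network: layer \code{observed}.  Null network: layer \code{null}
#' itself, rescaled to total weight \code{gamma * L}.  Pairs connected in both
#' layers lose weight in \code{B}, pairs connected only in the observed layer
#' keep it, and pairs connected only in the null layer become negative, so
#' maximizing modularity pushes overlapping edges out of communities.
#'
#' @param M a \code{multiplex} object.
#' @param observed,null layer names; must differ.
#' @param gamma null-strength multiplier (default 1).
#' @return A \code{modularity_matrix} with \code{mode = "exclusion"}.
#' @export
exclusion_matrix <- function(M, observed, null, gamma = 1) {
  stopifnot(inherits(M, "multiplex"))
  if (identical(observed, null))
    stopf("observed and null layer must differ (degenerate B = (1 - gamma*s) A)")
  obs <- get_layer(M, observed)
  nul <- get_layer(M, null)
  L <- total_weight(obs)
  if (L <= 0) stopf("observed layer '%s' has zero total weight", observed)
  P <- if (gamma == 0) 0 * nul$weights
       else normalize_null(nul$weights, L, gamma)
  new_modularity_matrix(B = obs$weights - P, P = P, L = L, gamma = gamma,
                        mode = "exclusion",
                        observed_layers = observed, null_layers = null)
}

#' Inclusion-mode modularity matrix: promote edge overlap
#'
#' Observed network: layer \code{observed}.  Null network: the binary
#' complement graph of layer \code{null}, rescaled to total weight
#' \code{gamma * L}.  Pairs connected in both layers are not penalized (the
#' complement is 0 there) while pairs missing from the null layer are, so
#' maximizing modularity favours communities whose edges are multidimensional.
#'
#' @inheritParams exclusion_matrix
#' @return A \code{modularity_matrix} with \code{mode = "inclusion"}.
#' @export
inclusion_matrix <- function(M, observed, null, gamma = 1) {
  stopifnot(inherits(M, "multiplex"))
  if (identical(observed, null))
    stopf("observed and null layer must differ")
  obs <- get_layer(M, observed)
  nul <- get_layer(M, null)
  if (!is_binary_matrix(nul$weights))
    stopf("null layer '%s' is not binary; use multi_matrix() for weighted nulls",
          null)
  L <- total_weight(obs)
  if (L <= 0) stopf("observed layer '%s' has zero total weight", observed)
  comp <- complement_binary(nul)
  P <- if (gamma == 0) 0 * comp$weights
       else normalize_null(comp$weights, L, gamma)
  new_modularity_matrix(B = obs$weights - P, P = P, L = L, gamma = gamma,
                        mode = "inclusion",
                        observed_layers = observed, null_layers = null)
}

#' Merged-multilayer modularity matrix: promote chosen layers
#'
#' Observed network: the weighted merge of the \code{observed} layers.  Null
#' network: the weighted complement graph (max-minus-weight, maximum taken
#' over the merged null sub-network) of the merge of the \code{null} layers,
#' rescaled to total weight \code{gamma * L}.  Maximizing modularity favours
#' communities in which the promoted (null) layers' edges are present.
#'
#' @param M a \code{multiplex} object.
#' @param observed character vector of layer names to merge as the observed
#'   network.
#' @param null character vector of layer names (a subset of \code{observed})
#'   whose presence inside communities is promoted.
#' @param gamma null-strength multiplier (default 1).
#' @return A \code{modularity_matrix} with \code{mode = "multi"}.
#' @export
multi_matrix <- function(M, observed, null, gamma = 1) {
  stopifnot(inherits(M, "multiplex"))
  if (length(observed) == 0 || length(null) == 0)
    stopf("'observed' and 'null' must each name at least one layer")
  if (!all(null %in% observed))
    stopf("null layers must be a subset of the observed layers")
  obs <- merge_layers(M, observed)
  L <- total_weight(obs)
  if (L <= 0) stopf("observed merge has zero total weight")
  comp <- complement_weighted(merge_layers(M, null))
  if (sum(comp$weights) <= 0)
    stopf("empty null: the weighted complement of '%s' has no weight",
          paste(null, collapse = "+"))
  P <- if (gamma == 0) 0 * comp$weights
       else normalize_null(comp$weights, L, gamma)
  new_modularity_matrix(B = obs$weights - P, P = P, L = L, gamma = gamma,
                        mode = "multi",
                        observed_layers = observed, null_layers = null)
}
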