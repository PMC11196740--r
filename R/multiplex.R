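# In-memory model of directed weighted multiplex networks: layers sharing one
# node set, layer merging, and binary/weighted complement graphs.

#' Create a network layer
#'
#' A layer is one directed, non-negatively weighted graph on an ordered node
#' set, stored as a dense adjacency matrix.  Entry \code{(i, j)} is the weight
#' of the directed edge \code{i -> j}; 0 means absent.  Self-loops are not
#' allowed: the diagonal must be zero.
#'
#' @param weights square numeric matrix of non-negative, finite weights with a
#'   zero diagonal.  Row/column names, if present, are the node identifiers.
#' @param name label for the layer.
#' @param nodes optional character vector of node identifiers overriding the
#'   matrix dimnames.
#' @return An object of class \code{mpx_layer} with fields \code{name},
#'   \code{nodes} and \code{weights}.
#' @examples
#' w <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' w["a", "b"] <- 1
#' mpx_layer(w, name = "advice")
#' @export
mpx_layer <- function(weights, name = "layer", nodes = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stopf("layer '%s': weight matrix must be square", name)
  n <- nrow(weights)
  if (!is.null(nodes)) {
    if (length(nodes) != n)
      stopf("layer '%s': %d node ids for a %d x %d matrix",
            name, length(nodes), n, n)
    dimnames(weights) <- list(nodes, nodes)
  } else if (is.null(rownames(weights))) {
    nodes <- sprintf("n%0*d", nchar(n), seq_len(n))
    dimnames(weights) <- list(nodes, nodes)
  } else {
    dimnames(weights) <- list(rownames(weights), rownames(weights))
  }
  if (any(!is.finite(weights)))
    stopf("layer '%s': weights must be finite", name)
  if (any(weights < 0))
    stopf("layer '%s': weights must be non-negative", name)
  if (any(diag(weights) != 0))
    stopf("layer '%s': self-loops are not allowed (non-zero diagonal)", name)
  structure(list(name = name, nodes = rownames(weights), weights = weights),
            class = "mpx_layer")
}

#' @export
print.mpx_layer <- function(x, ...) {
  cat(sprintf("<mpx_layer '%s'>  %d nodes, total weight L = %g\n",
              x$name, length(x$nodes), total_weight(x)))
  invisible(x)
}

#' Assemble a multiplex network from layers
#'
#' A multiplex network is a family of directed layers on one shared, ordered
#' node set with no interlayer edges.  The node order is fixed at construction
#' as the sorted union of node identifiers appearing in any layer; nodes
#' absent from a layer get all-zero rows and columns there.
#'
#' @param layers named list of \code{\link{mpx_layer}} objects or square
#'   numeric adjacency matrices (dimnames supply node ids).
#' @return An object of class \code{multiplex}: list with \code{nodes}
#'   (ordered character vector) and \code{layers} (named list of
#'   \code{mpx_layer}, all on the shared node order).
#' @examples
#' a <- matrix(0, 2, 2, dimnames = list(c("u", "v"), c("u", "v")))
#' a["u", "v"] <- 1
#' multiplex(list(coop = a, friend = t(a)))
#' @export
multiplex <- function(layers) {
  if (!is.list(layers) || length(layers) == 0)
    stopf("'layers' must be a non-empty list")
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stopf("'layers' must have unique non-empty names")
  layers <- lapply(seq_along(layers), function(i) {
    l <- layers[[i]]
    if (inherits(l, "mpx_layer")) mpx_layer(l$weights, name = nm[i])
    else mpx_layer(l, name = nm[i])
  })
  names(layers) <- nm
  nodes <- sort(unique(unlist(lapply(layers, `[[`, "nodes"))))
  layers <- lapply(layers, function(l) {
    w <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    w[l$nodes, l$nodes] <- l$weights
    mpx_layer(w, name = l$name)
  })
  structure(list(nodes = nodes, layers = layers), class = "multiplex")
}

#' @export
print.multiplex <- function(x, ...) {
  cat(sprintf("<multiplex>  %d nodes, %d layers\n",
              length(x$nodes), length(x$layers)))
  for (l in x$layers)
    cat(sprintf("  %-12s L = %g\n", l$name, total_weight(l)))
  invisible(x)
}

#' Names of the layers in a multiplex network
#' @param M a \code{multiplex} object.
#' @return Character vector of layer names.
#' @export
layer_names <- function(M) {
  stopifnot(inherits(M, "multiplex"))
  names(M$layers)
}

#' Extract one layer of a multiplex network
#' @param M a \code{multiplex} object.
#' @param name a layer name.
#' @return The \code{mpx_layer}.
#' @export
get_layer <- function(M, name) {
  stopifnot(inherits(M, "multiplex"))
  if (length(name) != 1 || !name %in% names(M$layers))
    stopf("unknown layer '%s' (available: %s)",
          paste(name, collapse = ","), paste(names(M$layers), collapse = ", "))
  M$layers[[name]]
}

#' Merge layers into one weighted layer
#'
#' Elementwise sum of the selected layers' weight matrices.  For binary
#' layers the merged weight of a pair counts in how many of the selected
#' dimensions the directed edge is present (e.g. weight 3 when an edge exists
#' in all three selected layers).
#'
#' @param M a \code{multiplex} object.
#' @param subset character vector of layer names to merge (non-empty).
#' @return An \code{mpx_layer} named after the subset, e.g. \code{"l1+l2"}.
#' @export
merge_layers <- function(M, subset) {
  stopifnot(inherits(M, "multiplex"))
  if (length(subset) == 0) stopf("'subset' must name at least one layer")
  missing <- setdiff(subset, names(M$layers))
  if (length(missing) > 0)
    stopf("unknown layer '%s'", missing[[1]])
  w <- Reduce(`+`, lapply(M$layers[subset], `[[`, "weights"))
  mpx_layer(w, name = paste(subset, collapse = "+"))
}

#' Total weight of a layer
#'
#' \eqn{L = \sum_{ij} A_{ij}}, the total edge mass of the directed layer.
#' For a binary layer this is the number of directed edges.
#'
#' @param layer an \code{mpx_layer}.
#' @return Non-negative number.
#' @export
total_weight <- function(layer) {
  stopifnot(inherits(layer, "mpx_layer"))
  sum(layer$weights)
}

#' Complement graph of a binary layer
#'
#' The complement has an edge exactly where the original has none: every
#' off-diagonal 1 becomes 0 and every off-diagonal 0 becomes 1.  The diagonal
#' stays zero (no self-loops).
#'
#' @param layer an \code{mpx_layer} with 0/1 weights.
#' @return An \code{mpx_layer} named \code{"~<name>"}.
#' @export
complement_binary <- function(layer) {
  stopifnot(inherits(layer, "mpx_layer"))
  w <- layer$weights
  if (!is_binary_matrix(w))
    stopf("layer '%s' is not binary; use complement_weighted()", layer$name)
  cw <- 1 - w
  diag(cw) <- 0
  mpx_layer(cw, name = paste0("~", layer$name))
}

#' Weighted complement graph of a layer
#'
#' Off-diagonal entries become \code{max(A) - A_ij}, where the maximum is the
#' global maximum off-diagonal weight of this layer.  Pairs carrying the
#' maximal weight (e.g. connected in every merged dimension) map to 0; absent
#' pairs map to the maximum.  The diagonal stays zero.
#'
#' @param layer an \code{mpx_layer} with at least one positive weight.
#' @return An \code{mpx_layer} named \code{"~<name>"}.
#' @export
complement_weighted <- function(layer) {
  stopifnot(inherits(layer, "mpx_layer"))
  w <- layer$weights
  mx <- max(w)
  if (mx <= 0)
    stopf("layer '%s' has no edges; its weighted complement is undefined",
          layer$name)
  cw <- mx - w
  diag(cw) <- 0
  mpx_layer(cw, name = paste0("~", layer$name))
}

#' Canonicalize a node partition
#'
#' A partition maps every node to a community id.  The canonical form uses
#' the contiguous integers \code{1..K}, assigned in order of first appearance
#' when scanning nodes in sorted identifier order.
#'
#' @param x named vector (names are node ids, values community labels of any
#'   type), or an unnamed vector with \code{nodes} supplied.
#' @param nodes optional node identifiers for an unnamed \code{x}.
#' @return Named integer vector with values in \code{1..K}, sorted by node
#'   identifier.
#' @examples
#' as_partition(c(b = "red", a = "blue", c = "red"))
#' @export
as_partition <- function(x, nodes = NULL) {
  if (is.null(names(x))) {
    if (is.null(nodes))
      stopf("partition must be named by node or 'nodes' must be given")
    if (length(nodes) != length(x))
      stopf("'nodes' length (%d) != partition length (%d)",
            length(nodes), length(x))
    names(x) <- nodes
  }
  if (anyDuplicated(names(x)))
    stopf("duplicate node identifiers in partition")
  if (any(is.na(x)))
    stopf("partition contains missing community labels")
  x <- x[order(names(x))]
  out <- match(x, unique(x))
  names(out) <- names(x)
  out
}

#' Number of communities in a partition
#' @param part a partition (see \code{\link{as_partition}}).
#' @return Integer count of distinct communities.
#' @export
n_communities <- function(part) length(unique(as_partition(part)))

# check a partition covers exactly the given node set; return it canonical
check_partition <- function(part, nodes) {
  part <- as_partition(part, nodes = if (is.null(names(part))) nodes)
  missing <- setdiff(nodes, names(part))
  if (length(missing) > 0)
    stopf("partition is missing node '%s'", missing[[1]])
  extra <- setdiff(names(part), nodes)
  if (length(extra) > 0)
    stopf("partition names unknown node '%s'", extra[[1]])
  part[nodes]
}
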