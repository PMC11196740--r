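# High-level fitting interface: build the modularity matrix for the requested
# mode and optimize it, returning a classed result with print/summary/plot
# methods.

new_multifacet <- function(partition, Q, matrix, method, seed, restarts_used,
                           trace, multiplex = NULL, call = NULL) {
  structure(list(partition = partition,
                 Q = Q,
                 K = length(unique(partition)),
                 matrix = matrix,
                 method = method,
                 seed = seed,
                 restarts_used = restarts_used,
                 trace = trace,
                 multiplex = multiplex,
                 call = call),
            class = "multifacet")
}

#' Detect multifaceted communities in a multiplex network
#'
#' Builds the modularity matrix \eqn{B = A - P} for the requested mode and
#' maximizes its modularity with the generalized Louvain optimizer.
#'
#' Modes:
#' \describe{
#'   \item{\code{"ng"}}{configuration-model null on the (merged)
#'     \code{observed} layers; the classical baseline.}
#'   \item{\code{"exclusion"}}{null = the \code{null} layer itself;
#'     communities avoid edges that overlap with the null layer.}
#'   \item{\code{"inclusion"}}{null = binary complement of the \code{null}
#'     layer; communities favour edges that co-occur with the null layer.}
#'   \item{\code{"multi"}}{observed = weighted merge of the \code{observed}
#'     layers, null = weighted complement of the merged \code{null} layers
#'     (a subset of \code{observed}); communities promote the chosen layers.}
#' }
#' In every mode the null is rescaled so that its total weight is
#' \code{gamma} times the observed total weight \eqn{L}.
#'
#' @param M a \code{\link{multiplex}} network.
#' @param mode one of \code{"ng"}, \code{"exclusion"}, \code{"inclusion"},
#'   \code{"multi"}.
#' @param observed observed layer name(s); \code{"ng"} and \code{"multi"}
#'   accept several (merged), \code{"exclusion"}/\code{"inclusion"} exactly
#'   one.
#' @param null null layer name(s); unused for \code{"ng"}, exactly one for
#'   \code{"exclusion"}/\code{"inclusion"}, a subset of \code{observed} for
#'   \code{"multi"}.
#' @param gamma null-strength multiplier (default 1).
#' @param degree_mode degree convention for the configuration null
#'   (\code{"total"} or \code{"directed"}; see
#'   \code{\link{configuration_null}}).
#' @param seed,restarts,node_order passed to \code{\link{louvain}}.
#' @return An object of class \code{multifacet}; see \code{\link{louvain}}.
#' @examples
#' M <- fig1_toy()
#' fit <- multifacet(M, mode = "exclusion", observed = "black",
#'                   null = "red", seed = 1)
#' print(fit)
#' summary(fit, base = "black", cond = "red")
#' @export
multifacet <- function(M,
                       mode = c("ng", "exclusion", "inclusion", "multi"),
                       observed = layer_names(M),
                       null = NULL,
                       gamma = 1,
                       degree_mode = c("total", "directed"),
                       seed = 1L,
                       restarts = 20L,
                       node_order = c("shuffled", "sorted")) {
  stopifnot(inherits(M, "multiplex"))
  mode <- match.arg(mode)
  degree_mode <- match.arg(degree_mode)
  one <- function(x, what) {
    if (length(x) != 1)
      stopf("mode '%s' needs exactly one %s layer", mode, what)
    x
  }
  Bm <- switch(mode,
    ng = {
      if (!is.null(null))
        stopf("mode 'ng' uses the configuration model; 'null' must be NULL")
      configuration_null(merge_layers(M, observed), degree_mode = degree_mode)
    },
    exclusion = exclusion_matrix(M, one(observed, "observed"),
                                 one(null, "null"), gamma = gamma),
    inclusion = inclusion_matrix(M, one(observed, "observed"),
                                 one(null, "null"), gamma = gamma),
    multi = multi_matrix(M, observed, null, gamma = gamma))
  fit <- louvain(Bm, seed = seed, restarts = restarts,
                 node_order = match.arg(node_order))
  fit$multiplex <- M
  fit$call <- match.call()
  fit
}

#' @export
print.multifacet <- function(x, ...) {
  cat("Multifaceted community detection\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  Bm <- x$matrix
  cat(sprintf("Mode: %s   observed: %s%s   gamma = %g\n",
              Bm$mode, paste(Bm$observed_layers, collapse = "+"),
              if (length(Bm$null_layers))
                paste0("   null: ", paste(Bm$null_layers, collapse = "+"))
              else "",
              Bm$gamma))
  cat(sprintf("N = %d nodes, K = %d communities, Q = %.4f (%s%s)\n",
              length(x$partition), x$K, x$Q, x$method,
              if (!is.na(x$restarts_used))
                sprintf(", %d restarts, seed %s", x$restarts_used, x$seed)
              else ""))
  sizes <- sort(table(x$partition), decreasing = TRUE)
  cat("Community sizes:", paste(as.integer(sizes), collapse = " "), "\n")
  invisible(x)
}

#' Summarize a detection result module by module
#'
#' One row per community: size, local modularity \eqn{Q_c}, and (when a base
#' and conditioning layer are given) the within-module edge-overlap
#' probability \eqn{P(cond | base)}.
#'
#' @param object a \code{multifacet} fit.
#' @param base,cond optional binary layer names for the within-module overlap
#'   probability (see \code{\link{overlap_probability}}).
#' @param ... unused.
#' @return A \code{summary.multifacet} object wrapping the module table.
#' @export
summary.multifacet <- function(object, base = NULL, cond = NULL, ...) {
  tab <- module_summary(object$matrix, object$partition,
                        M = object$multiplex, base = base, cond = cond)
  structure(list(table = tab, Q = object$Q, K = object$K,
                 mode = object$matrix$mode, gamma = object$matrix$gamma,
                 base = base, cond = cond),
            class = "summary.multifacet")
}

#' @export
print.summary.multifacet <- function(x, ...) {
  cat(sprintf("Mode %s (gamma = %g): K = %d communities, global Q = %.4f\n",
              x$mode, x$gamma, x$K, x$Q))
  if (!is.null(x$base))
    cat(sprintf("Overlap column: P(%s | %s) within module\n", x$cond, x$base))
  tab <- x$table
  tab$Q_c <- round(tab$Q_c, 4)
  if (!all(is.na(tab$overlap_prob)))
    tab$overlap_prob <- round(tab$overlap_prob, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Plot a detection result
#'
#' Displays the observed part of the modularity construction (the matrix
#' \eqn{A}, i.e. \eqn{B + P}) with nodes ordered by community, so detected
#' modules appear as blocks on the diagonal.
#'
#' @param x a \code{multifacet} fit.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @return Invisibly, the node order used.
#' @export
plot.multifacet <- function(x, ...) {
  A <- x$matrix$B + x$matrix$P
  ord <- order(x$partition, names(x$partition))
  A <- A[ord, ord]
  n <- nrow(A)
  graphics::image(seq_len(n), seq_len(n), t(A[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  xlab = "", ylab = "", axes = FALSE, ...)
  brk <- cumsum(table(x$partition[ord])) + 0.5
  graphics::abline(v = brk, h = n - brk + 1, col = "grey40", lty = 2)
  graphics::box()
  invisible(ord)
}
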