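# Layered edge-list file format and table writers.
#
# The canonical on-disk form of a multiplex network is a delimiter-separated
# file with header `source,target,layer,weight`; the weight column is
# optional (default 1).  Node identifiers are arbitrary strings.  This is the
# natural shape for sparse directed multiplex data; a square-matrix text dump
# per layer can be converted with as_multiplex_matrices().

#' Read a multiplex network from a layered edge list
#'
#' Parses a CSV file with columns \code{source,target,layer} and optional
#' \code{weight} (default 1).  Duplicate \code{(source, target, layer)} rows
#' are summed with a warning.  Self-loops, negative weights and missing
#' columns are rejected with the offending row number.
#'
#' @param path path to the file.
#' @return A \code{\link{multiplex}} network; node order is the sorted union
#'   of identifiers seen in any layer.
#' @export
read_multiplex <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  need <- c("source", "target", "layer")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stopf("missing column(s): %s", paste(missing, collapse = ", "))
  if (nrow(df) == 0) stopf("edge list is empty")
  if ("weight" %in% names(df)) {
    w <- suppressWarnings(as.numeric(df$weight))
    if (any(is.na(w)))
      stopf("non-numeric weight at row %d", which(is.na(w))[1])
  } else {
    w <- rep(1, nrow(df))
  }
  if (any(w < 0))
    stopf("negative weight at row %d", which(w < 0)[1])
  loops <- df$source == df$target
  if (any(loops))
    stopf("self-loop at row %d (node '%s')", which(loops)[1],
          df$source[which(loops)[1]])
  key <- paste(df$source, df$target, df$layer, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate (source,target,layer) rows summed",
                    sum(duplicated(key))), call. = FALSE)
  }
  nodes <- sort(unique(c(df$source, df$target)))
  layer_nms <- unique(df$layer)
  layers <- lapply(layer_nms, function(lname) {
    sel <- df$layer == lname
    m <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    idx <- cbind(match(df$source[sel], nodes), match(df$target[sel], nodes))
    for (r in seq_len(nrow(idx)))
      m[idx[r, 1], idx[r, 2]] <- m[idx[r, 1], idx[r, 2]] + w[sel][r]
    m
  })
  names(layers) <- layer_nms
  multiplex(layers)
}

#' Convert per-layer adjacency matrices to a multiplex network
#'
#' Converter for data shipped as one square matrix (plain text dump) per
#' layer rather than an edge list.
#'
#' @param mats named list of square numeric matrices.
#' @return A \code{\link{multiplex}} network.
#' @export
as_multiplex_matrices <- function(mats) multiplex(mats)

#' Write a multiplex network as a layered edge list
#'
#' Inverse of \code{\link{read_multiplex}} up to canonical row ordering
#' (layer, then source, then target).
#'
#' @param M a \code{\link{multiplex}} network.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_multiplex <- function(M, path) {
  stopifnot(inherits(M, "multiplex"))
  rows <- lapply(names(M$layers), function(lname) {
    w <- M$layers[[lname]]$weights
    nz <- which(w != 0, arr.ind = TRUE)
    if (nrow(nz) == 0) return(NULL)
    data.frame(source = rownames(w)[nz[, 1]],
               target = colnames(w)[nz[, 2]],
               layer = lname,
               weight = w[nz],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) stopf("network has no edges to write")
  df <- df[order(df$layer, df$source, df$target), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a partition as node,community rows
#' @param part a partition (see \code{\link{as_partition}}).
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_partition <- function(part, path) {
  part <- as_partition(part)
  df <- data.frame(node = names(part), community = unname(part))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a partition written by write_partition
#' @param path path to a \code{node,community} CSV file.
#' @return A canonical named partition vector.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("node", "community") %in% names(df)))
    stopf("partition file needs columns node,community")
  as_partition(stats::setNames(df$community, df$node))
}

#' Write a module summary table
#'
#' Columns \code{community,n_members,Q_c,overlap_prob}; reals in fixed
#' 6-decimal form, undefined overlap written as \code{NA}.
#'
#' @param rows data frame from \code{\link{module_summary}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_summary <- function(rows, path) {
  lines <- c("community,n_members,Q_c,overlap_prob",
             sprintf("%s,%d,%s,%s", rows$community, rows$n_members,
                     fmt_real(rows$Q_c), fmt_real(rows$overlap_prob)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a layer-contribution scan table
#'
#' Columns \code{promoted_layers,Q,nmi}; reals in fixed 6-decimal form,
#' degenerate rows as \code{NA}.
#'
#' @param rows data frame from \code{\link{layer_contribution_scan}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_scan <- function(rows, path) {
  lines <- c("promoted_layers,Q,nmi",
             sprintf("%s,%s,%s", rows$promoted_layers,
                     fmt_real(rows$Q), fmt_real(rows$nmi)))
  writeLines(lines, path)
  invisible(path)
}
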