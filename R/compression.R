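#' Lambda-type of a hyperedge under a cluster assignment
#'
#' The lambda-type of edge `A` is the vector with `lambda[i] = |A` \eqn{\cap}
#' `C_i|`, counted with multiplicity: the signature of how the edge
#' intersects the clusters.
#'
#' @param edge integer vector of vertex indices (repeats allowed).
#' @param labels integer cluster labels in `1..m`, one per vertex.
#' @param m label budget (number of available clusters).
#' @return integer vector of length `m`; entry `i` counts the members of the
#'   edge in cluster `i`, so `sum(lambda_type(...)) == length(edge)`.
#' @export
#' @examples
#' lambda_type(c(1, 2, 3), c(1, 1, 3), m = 3)  # 2 0 1
lambda_type <- function(edge, labels, m) {
  lab <- labels[edge]
  if (anyNA(lab)) stop("edge contains an unlabeled vertex")
  tabulate(lab, nbins = m)
}

# sparse canonical key of a type: the sorted cluster labels of the edge's
# members, e.g. "1 1 2" for lambda = (2, 1).  Keys are comparable across
# edges of any size and m.
lambda_key <- function(edge, labels) {
  paste(sort(labels[edge]), collapse = " ")
}

key_to_lambda <- function(key, m) {
  tabulate(as.integer(strsplit(key, " ", fixed = TRUE)[[1L]]), nbins = m)
}

#' Compress a hypergraph under a cluster assignment
#'
#' A compression is the lossy summary of a hypergraph retained by the
#' blockmodel: the cluster sizes and the count `e_lambda` of edges of each
#' lambda-type; a degree-corrected compression additionally retains the
#' per-vertex degree sequence.
#'
#' @param h a [hypergraph()].
#' @param labels integer cluster labels in `1..m`.
#' @param m label budget; empty clusters are permitted. Defaults to
#'   `max(labels)`.
#' @param with_degrees include the degree sequence (degree-corrected
#'   compression).
#' @return An object of class `"hg_compression"`: `cluster_sizes` (length
#'   `m`), `e_lambda` (named integer vector of type counts; names are
#'   canonical type keys), `lambda` (list of dense lambda vectors parallel
#'   to `e_lambda`), `e_i` (per-cluster degree sums
#'   \eqn{e_i = \sum_\lambda \lambda_i e_\lambda}), `degrees` (or `NULL`),
#'   `n`, `n_edges`, `m`.
#' @export
compress <- function(h, labels, m = max(labels), with_degrees = FALSE) {
  stopifnot(inherits(h, "hypergraph"))
  labels <- as.integer(labels)
  if (length(labels) != h$n) stop("`labels` must label every vertex of `h`")
  if (anyNA(labels) || any(labels < 1L) || any(labels > m))
    stop("labels must lie in 1..m")
  keys <- vapply(h$edges, lambda_key, "", labels = labels)
  tab <- table(keys)
  key_names <- names(tab)
  lambda <- lapply(key_names, key_to_lambda, m = m)
  e_lambda <- as.integer(tab)
  names(e_lambda) <- key_names
  e_i <- if (length(lambda)) {
    as.numeric(Reduce(`+`, Map(`*`, lambda, e_lambda)))
  } else rep(0, m)
  structure(
    list(cluster_sizes = tabulate(labels, nbins = m),
         e_lambda = e_lambda, lambda = lambda, e_i = e_i,
         degrees = if (with_degrees) h$degrees else NULL,
         n = h$n, n_edges = length(h$edges), m = as.integer(m)),
    class = "hg_compression")
}

#' @export
print.hg_compression <- function(x, ...) {
  cat("compression into m = ", x$m, " clusters",
      if (!is.null(x$degrees)) " (degree-corrected)", "\n", sep = "")
  cat("cluster sizes:", x$cluster_sizes, "\n")
  cat("lambda-types: ", length(x$e_lambda), " realized, ",
      x$n_edges, " edges\n", sep = "")
  invisible(x)
}

#' Module matrix of a 2-uniform hypergraph
#'
#' `M[i, j]` counts the edges with one endpoint in cluster `i` and the other
#' in cluster `j` (`i != j`); `M[i, i]` counts the edges within cluster `i`.
#' A self-loop edge `{v, v}` counts toward `M[c_v, c_v]`.
#'
#' @inheritParams compress
#' @return symmetric `m` x `m` integer matrix with
#'   `sum(M[upper.tri(M, diag = TRUE)])` equal to the edge count.
#' @export
module_matrix <- function(h, labels, m = max(labels)) {
  stopifnot(inherits(h, "hypergraph"))
  if (any(lengths(h$edges) != 2L)) stop("module matrix requires a 2-uniform hypergraph")
  labels <- as.integer(labels)
  M <- matrix(0L, m, m)
  for (e in h$edges) {
    i <- labels[e[1L]]; j <- labels[e[2L]]
    M[i, j] <- M[i, j] + 1L
    if (i != j) M[j, i] <- M[j, i] + 1L
  }
  M
}
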