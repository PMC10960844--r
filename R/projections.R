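#' Clique projections of a hypergraph
#'
#' `simple_projection` replaces the hyperedges by a single pairwise edge for
#' every pair of distinct vertices that co-occur in at least one hyperedge.
#' `multiedge_projection` keeps multiplicities: a pair of vertices that
#' co-occur in `k` hyperedges is joined by `k` parallel dyadic edges.
#' Both projections preserve the vertex set and order, and neither emits
#' self-loops: a repeated vertex within one hyperedge contributes no
#' `{v, v}` dyad.
#'
#' @param h a [hypergraph()].
#' @param count_parallel for `multiedge_projection`, whether parallel
#'   hyperedges each count toward the dyad multiplicity (default) or
#'   hyperedges are first deduplicated.  Irrelevant for simple input.
#' @return a 2-uniform [hypergraph()] on the same vertex set; simple for
#'   `simple_projection`, a multigraph in general for
#'   `multiedge_projection`.
#' @export
#' @examples
#' h <- hypergraph(list(c(1, 2), c(1, 2, 3)))
#' length(simple_projection(h)$edges)     # 3: {1,2},{1,3},{2,3}
#' length(multiedge_projection(h)$edges)  # 4: {1,2} twice
simple_projection <- function(h) {
  stopifnot(inherits(h, "hypergraph"))
  pairs <- edge_pair_list(h$edges)
  if (length(pairs)) pairs <- pairs[!duplicated(edge_keys(pairs))]
  hypergraph(pairs, n = h$n, vertex_names = h$vertex_names)
}

#' @rdname simple_projection
#' @export
multiedge_projection <- function(h, count_parallel = TRUE) {
  stopifnot(inherits(h, "hypergraph"))
  edges <- h$edges
  if (!count_parallel) edges <- edges[!duplicated(edge_keys(edges))]
  hypergraph(edge_pair_list(edges), n = h$n, vertex_names = h$vertex_names)
}

# all unordered pairs of distinct vertices within each (sorted) edge
edge_pair_list <- function(edges) {
  out <- lapply(edges, function(e) {
    u <- unique(e)
    if (length(u) < 2L) return(NULL)
    cm <- utils::combn(u, 2L)
    lapply(seq_len(ncol(cm)), function(j) cm[, j])
  })
  out <- unlist(out, recursive = FALSE)
  if (is.null(out)) list() else out
}
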