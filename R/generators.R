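#' Planted-partition benchmark hypergraph
#'
#' Generates a simple hypergraph with two ground-truth communities of `n`
#' vertices each, exactly `5 * n` 2-edges and `round(10 * n / 3)` 3-edges,
#' so every vertex sees on average five 2-edges and five 3-edges.  A
#' proportion `p2` of the 2-edges lies within a community (split as evenly
#' as possible between the two, remainder to community 1) and the rest span
#' both; a proportion `p3` of the 3-edges lies fully within a community,
#' and the rest are of type (2,1)/(1,2) with the majority side alternating
#' so that within- and between-community edge placement stays balanced.
#' Edges have distinct vertices and no duplicates (rejection sampling), so
#' the output is simple.
#'
#' @param n community size; the hypergraph has `2 * n` vertices.
#' @param p2,p3 within-community proportions of 2-edges and 3-edges, in
#'   `[0, 1]`.
#' @param seed optional integer seed.
#' @param max_tries rejection-sampling retry budget per edge category.
#' @return list with elements `hypergraph` and `labels` (ground truth,
#'   `1` for vertices `1..n`, `2` for the rest).
#' @export
planted_partition <- function(n = 200L, p2, p3, seed = NULL, max_tries = 200L) {
  stopifnot(n >= 3, p2 >= 0, p2 <= 1, p3 >= 0, p3 <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  A <- seq_len(n)
  B <- n + seq_len(n)
  n2 <- 5L * n
  n3 <- as.integer(round(10 * n / 3))
  w2 <- as.integer(round(p2 * n2)); b2 <- n2 - w2
  w3 <- as.integer(round(p3 * n3)); b3 <- n3 - w3
  w2A <- as.integer(ceiling(w2 / 2)); w2B <- w2 - w2A
  w3A <- as.integer(ceiling(w3 / 2)); w3B <- w3 - w3A
  b3A <- as.integer(ceiling(b3 / 2)); b3B <- b3 - b3A # (2,1) vs (1,2) majority
  if (w2A > choose(n, 2) || b2 > n^2 || w3A > choose(n, 3) ||
      b3A > choose(n, 2) * n)
    stop("requested edge counts infeasible for community size n = ", n)

  seen <- new.env(parent = emptyenv())
  draw <- function(k, blocks) {
    # k distinct-vertex edges sampled uniformly from the block structure
    # (each element of `blocks` is the vertex pool of one edge slot),
    # rejecting repeated vertices and globally duplicate edges
    out <- vector("list", k)
    got <- 0L
    for (try in seq_len(max_tries)) {
      if (got >= k) break
      need <- (k - got) * 2L + 8L
      cand <- do.call(cbind, lapply(blocks, function(bl)
        bl[sample.int(length(bl), need, replace = TRUE)]))
      cand <- cand[!apply(cand, 1L, anyDuplicated), , drop = FALSE]
      if (!nrow(cand)) next
      cand <- t(apply(cand, 1L, sort))
      keys <- apply(cand, 1L, paste, collapse = " ")
      for (r in seq_along(keys)) {
        if (got >= k) break
        if (is.null(seen[[keys[r]]])) {
          assign(keys[r], TRUE, envir = seen)
          got <- got + 1L
          out[[got]] <- as.integer(cand[r, ])
        }
      }
    }
    if (got < k) stop("rejection sampling failed; edge counts too dense for n = ", n)
    out
  }
  edges <- c(
    if (w2A > 0) draw(w2A, list(A, A)),
    if (w2B > 0) draw(w2B, list(B, B)),
    if (b2 > 0) draw(b2, list(A, B)),
    if (w3A > 0) draw(w3A, list(A, A, A)),
    if (w3B > 0) draw(w3B, list(B, B, B)),
    if (b3A > 0) draw(b3A, list(A, A, B)),
    if (b3B > 0) draw(b3B, list(A, B, B)))
  list(hypergraph = hypergraph(edges, n = 2L * n),
       labels = rep(1:2, each = n))
}

#' Degree-corrected hypergraph stochastic blockmodel benchmark
#'
#' Generates a hypergraph with heterogeneous, cluster-uninformative vertex
#' degrees.  Each vertex receives a propensity `theta_v = 1 / r_v` with
#' `r_v` uniform on `{1, ..., r_max}`.  For every sub-multiset `R` of the
#' vertices of size 2 or 3 (repeated vertices allowed), an edge count is
#' drawn as `X_R ~ Poisson(rate(R))` with
#' `rate(R) = orderings(R) * prod(theta[R]) * Omega(R)`, where `Omega` is
#' the all-or-nothing intensity (`omega_in` when all members of `R`, with
#' multiplicity, lie in one ground-truth cluster, `omega_out` otherwise),
#' and `orderings(R)` is the number of distinct orderings of the multiset
#' (`rate_convention = "ordered"`, the default: intensities are specified
#' per ordered tuple and aggregated per multiset, the convention of the
#' degree-corrected blockmodel family this generator follows;
#' `"multiset"` sets `orderings = 1`).  `R` becomes an edge (once) iff
#' `X_R > 0`.  Every edge supported on a single vertex `v` is then replaced
#' by the 2-edge `{v, (v mod N) + 1}`, and duplicate edges arising from the
#' replacement are removed, so the output has no parallel edges.  Edges
#' with a repeated vertex but two distinct members (e.g. `{v, v, u}`) are
#' kept as-is by default; `keep_multiset_edges = FALSE` collapses their
#' repeats and drops any resulting duplicates.
#'
#' @param cluster_sizes integer vector of ground-truth cluster sizes.
#' @param r_max propensities are `1 / r` with `r` uniform on `{1..r_max}`.
#' @param omega_in,omega_out within- and between-cluster intensities.
#' @param seed optional integer seed.
#' @param rate_convention `"ordered"` (default) or `"multiset"`; see above.
#' @param keep_multiset_edges keep edges like `{v, v, u}` as multisets.
#' @param theta optional explicit propensity vector (overrides `r_max`
#'   sampling; useful for calibration checks).
#' @return list with elements `hypergraph`, `labels` (ground truth),
#'   `theta` and `r` (`NA` when `theta` was supplied).
#' @export
dchsbm <- function(cluster_sizes = c(50L, 50L), r_max = 24L,
                   omega_in = 1, omega_out = 0.1, seed = NULL,
                   rate_convention = c("ordered", "multiset"),
                   keep_multiset_edges = TRUE, theta = NULL) {
  rate_convention <- match.arg(rate_convention)
  stopifnot(omega_in > omega_out, omega_out >= 0)
  if (!is.null(seed)) set.seed(seed)
  N <- sum(cluster_sizes)
  if (N > 500) stop("sub-multiset enumeration is intended for N <= 500")
  labels <- rep(seq_along(cluster_sizes), cluster_sizes)
  r <- rep(NA_integer_, N)
  if (is.null(theta)) {
    r <- sample.int(r_max, N, replace = TRUE)
    theta <- 1 / r
  }
  stopifnot(length(theta) == N, all(theta > 0), all(theta <= 1))

  # size-2 sub-multisets: i <= j
  i2 <- rep.int(seq_len(N), rev(seq_len(N)))
  j2 <- unlist(lapply(seq_len(N), function(i) i:N))
  within2 <- labels[i2] == labels[j2]
  ord2 <- if (rate_convention == "ordered") ifelse(i2 == j2, 1, 2) else 1
  rate2 <- ord2 * theta[i2] * theta[j2] * ifelse(within2, omega_in, omega_out)
  keep2 <- stats::rpois(length(rate2), rate2) > 0

  # size-3 sub-multisets i <= j <= k via the stars-and-bars bijection
  cmb <- utils::combn(N + 2L, 3L)
  i3 <- cmb[1L, ]; j3 <- cmb[2L, ] - 1L; k3 <- cmb[3L, ] - 2L
  within3 <- labels[i3] == labels[j3] & labels[j3] == labels[k3]
  ord3 <- if (rate_convention == "ordered") {
    ifelse(i3 == j3 & j3 == k3, 1, ifelse(i3 == j3 | j3 == k3, 3, 6))
  } else 1
  rate3 <- ord3 * theta[i3] * theta[j3] * theta[k3] *
    ifelse(within3, omega_in, omega_out)
  keep3 <- stats::rpois(length(rate3), rate3) > 0

  e2 <- Map(c, i2[keep2], j2[keep2])
  e3 <- Map(c, i3[keep3], j3[keep3], k3[keep3])
  edges <- c(e2, e3)
  # single-support edges {v,v} / {v,v,v} -> {v, (v mod N) + 1}
  edges <- lapply(edges, function(e) {
    u <- unique(e)
    if (length(u) == 1L) sort(c(u, (u %% N) + 1L)) else e
  })
  if (!keep_multiset_edges) {
    edges <- lapply(edges, unique)
    edges <- edges[lengths(edges) >= 2L]
  }
  edges <- edges[!duplicated(edge_keys(lapply(edges, sort)))]
  list(hypergraph = hypergraph(edges, n = N), labels = labels,
       theta = theta, r = r)
}
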