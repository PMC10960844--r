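# All entropies are natural-log counts (nats).  Conversion to bits happens
# only in description_length().  Factorials and binomials go through
# lgamma/lchoose; no big-integer arithmetic (counts overflow integers long
# before n = 400).

# log C(N, k) for a possibly huge, possibly non-integer N given as logN.
# For small k the explicit product avoids the lgamma(N) - lgamma(N - k)
# cancellation; for logN > 500, exp(logN) would overflow and the k-term
# expansion log C(N,k) ~ k logN - log k! is exact to O(k^2/N).
simple_type_term <- function(logN, k, strict = FALSE) {
  if (k == 0) return(0)
  if (logN > 500) return(k * logN - lgamma(k + 1))
  N <- exp(logN)
  if (k > N + 1e-9) {
    if (strict) stop("compression infeasible for simple model (e_lambda > N_lambda)")
    return(Inf) # zero compatible hypergraphs: forbidden state
  }
  if (k < 64) sum(log(N - seq_len(k) + 1)) - lgamma(k + 1) else lchoose(N, k)
}

#' Compression entropies log Z(gamma)
#'
#' `log Z(gamma)` is the natural logarithm of the number of hypergraphs
#' compatible with the compression `gamma` -- the conditional entropy of the
#' hypergraph given its compression, and the objective minimized by
#' [anneal()].  Four counting models are available:
#'
#' * `log_z_simple`: simple hypergraphs (no parallel edges);
#'   \eqn{Z = \prod_\lambda \binom{N_\lambda}{e_\lambda}} with
#'   \eqn{N_\lambda = \prod_i \binom{|C_i|}{\lambda_i}}.
#' * `log_z_multiset`: multi-hypergraphs (parallel edges allowed);
#'   \eqn{Z = \prod_{A \in E} \prod_i \binom{|C_i|}{|A \cap C_i|}}.
#' * `log_z_degree_corrected`: distinguishable-stub count with the degree
#'   sequence held fixed;
#'   \eqn{Z = \prod_i e_i! \; / \; (\prod_\lambda e_\lambda! \;
#'   \prod_\lambda \prod_i (\lambda_i!)^{e_\lambda})}.  This stub count
#'   permits repeated vertex inclusions and parallel edges, so it is an
#'   approximation of the exact degree-corrected count; its value may be
#'   negative.
#' * `log_z_graph`: module-matrix count for 2-uniform graphs;
#'   \eqn{Z = \prod_{i<j} \binom{|C_i||C_j|}{M_{ij}} \prod_i
#'   \binom{\binom{|C_i|}{2}}{M_{ii}}}.  On simple 2-uniform input it equals
#'   `log_z_simple`.
#'
#' @param comp an [compress()] result (`log_z_degree_corrected` requires one
#'   built with `with_degrees = TRUE`).
#' @return the entropy in nats; nonnegative for the simple, multiset and
#'   graph counts whenever the compression is feasible.
#' @seealso [log_z()] for the one-call interface from a hypergraph and
#'   labels, [delta_log_z()] for single-vertex move differences.
#' @export
log_z_simple <- function(comp) {
  stopifnot(inherits(comp, "hg_compression"))
  total <- 0
  for (t in seq_along(comp$lambda)) {
    logN <- sum(lchoose(comp$cluster_sizes, comp$lambda[[t]]))
    if (!is.finite(logN))
      stop("compression infeasible for simple model (lambda_i > |C_i|)")
    total <- total + simple_type_term(logN, comp$e_lambda[[t]], strict = TRUE)
  }
  total
}

#' @rdname log_z_simple
#' @export
log_z_multiset <- function(comp) {
  stopifnot(inherits(comp, "hg_compression"))
  total <- 0
  for (t in seq_along(comp$lambda)) {
    per_edge <- sum(lchoose(comp$cluster_sizes, comp$lambda[[t]]))
    if (!is.finite(per_edge))
      stop("compression infeasible for multiset model (lambda_i > |C_i|)")
    total <- total + comp$e_lambda[[t]] * per_edge
  }
  total
}

#' @rdname log_z_simple
#' @export
log_z_degree_corrected <- function(comp) {
  stopifnot(inherits(comp, "hg_compression"))
  if (is.null(comp$degrees))
    stop("degree-corrected model requires degree sequence (compress with with_degrees = TRUE)")
  total <- sum(lgamma(comp$e_i + 1))
  for (t in seq_along(comp$lambda)) {
    cnt <- comp$e_lambda[[t]]
    lam <- comp$lambda[[t]]
    total <- total - lgamma(cnt + 1) - cnt * sum(lgamma(lam + 1))
  }
  total
}

# Step-by-step factorization of the degree-corrected count: the lambda-type
# stub assignment a(gamma) times the packet-and-combine factor c(gamma).
# Used as an independent route in tests; algebraically equal to
# log_z_degree_corrected.
log_z_dc_factored <- function(comp) {
  if (is.null(comp$degrees)) stop("degree-corrected model requires degree sequence")
  m <- comp$m
  cnts <- comp$e_lambda
  lam_mat <- if (length(comp$lambda)) do.call(cbind, comp$lambda) else matrix(0, m, 0)
  # a(gamma) = prod_i multinomial(e_i ; ..., lambda_i e_lambda, ...)
  log_a <- sum(lgamma(comp$e_i + 1)) - sum(lgamma(sweep(lam_mat, 2, cnts, `*`) + 1))
  # p_lambda(gamma) = prod_i (lambda_i e_lambda)! / (lambda_i!)^{e_lambda}
  log_c <- 0
  for (t in seq_along(comp$lambda)) {
    lam <- comp$lambda[[t]]; cnt <- cnts[[t]]
    log_p <- sum(lgamma(lam * cnt + 1) - cnt * lgamma(lam + 1))
    log_c <- log_c - lgamma(cnt + 1) + log_p
  }
  log_a + log_c
}

#' @rdname log_z_simple
#' @param mm module matrix as returned by [module_matrix()].
#' @param cluster_sizes integer vector of cluster sizes \eqn{|C_i|}.
#' @export
log_z_graph <- function(mm, cluster_sizes) {
  m <- length(cluster_sizes)
  stopifnot(is.matrix(mm), nrow(mm) == m, ncol(mm) == m)
  total <- 0
  for (i in seq_len(m)) {
    Nii <- choose(cluster_sizes[i], 2)
    if (mm[i, i] > Nii) stop("infeasible within-cluster edge count")
    total <- total + simple_type_term(log(max(Nii, 1)), mm[i, i], strict = TRUE)
    for (j in seq_len(m)[-seq_len(i)]) {
      Nij <- as.numeric(cluster_sizes[i]) * cluster_sizes[j]
      if (mm[i, j] > Nij) stop("infeasible between-cluster edge count")
      total <- total + simple_type_term(log(max(Nij, 1)), mm[i, j], strict = TRUE)
    }
  }
  total
}

#' Compression entropy of a labeled hypergraph
#'
#' Convenience wrapper: compress `h` under `labels` and evaluate the chosen
#' counting model.
#'
#' @inheritParams compress
#' @param model counting model; `"graph"` requires 2-uniform input and is
#'   evaluated through the module-matrix count.
#' @return entropy in nats.
#' @export
log_z <- function(h, labels, m = max(labels),
                  model = c("degree_corrected", "simple", "multiset", "graph")) {
  model <- match.arg(model)
  if (model == "graph") {
    return(log_z_graph(module_matrix(h, labels, m), tabulate(as.integer(labels), m)))
  }
  comp <- compress(h, labels, m, with_degrees = model == "degree_corrected")
  switch(model,
         simple = log_z_simple(comp),
         multiset = log_z_multiset(comp),
         degree_corrected = log_z_degree_corrected(comp))
}

#' Incremental entropy bookkeeping for single-vertex moves
#'
#' `entropy_state` builds the live compression state (type table, cluster
#' sizes, degree sums, cached entropy) for a labeled hypergraph;
#' `delta_log_z` evaluates `log Z(c') - log Z(c)` for the move that
#' relabels vertex `v` to cluster `i`, touching only the lambda-types of
#' edges incident to `v` and the per-cluster terms of the two clusters
#' involved -- it never rebuilds the compression.
#'
#' @inheritParams log_z
#' @return `entropy_state`: an object of class `"hg_entropy_state"`.
#'   `delta_log_z`: a single numeric; `+Inf` if the move would make the
#'   compression infeasible under the simple model.
#' @export
entropy_state <- function(h, labels, m = max(labels),
                          model = c("degree_corrected", "simple", "multiset")) {
  model <- match.arg(model)
  labels <- as.integer(labels)
  keys <- vapply(h$edges, lambda_key, "", labels = labels)
  tab <- table(keys)
  counts <- as.numeric(tab)
  names(counts) <- names(tab)
  nedge <- length(h$edges)
  inc <- rep(list(integer(0)), h$n)
  if (nedge) {
    by_vertex <- split(rep(seq_len(nedge), lengths(h$edges)), unlist(h$edges))
    inc[as.integer(names(by_vertex))] <- lapply(by_vertex, unique)
  }
  st <- list(h = h, labels = labels, m = as.integer(m), model = model,
             sizes = tabulate(labels, m), counts = counts, edge_key = keys,
             inc = inc,
             e_i = vapply(seq_len(m), function(i)
               sum(h$degrees[labels == i]), 0))
  st$log_z <- log_z(h, labels, m, model)
  class(st) <- "hg_entropy_state"
  st
}

# entropy contribution of one type-table (keys -> counts) under sizes;
# excludes the degree-corrected sum_i lgamma(e_i + 1) part.
type_table_log_z <- function(keys, counts, sizes, m, model) {
  total <- 0
  for (t in seq_along(counts)) {
    cnt <- counts[[t]]
    if (cnt <= 0) next
    lam <- key_to_lambda(keys[[t]], m)
    if (model == "degree_corrected") {
      total <- total - lgamma(cnt + 1) - cnt * sum(lgamma(lam + 1))
    } else {
      per <- sum(lchoose(sizes, lam))
      if (!is.finite(per)) return(Inf)
      total <- total +
        if (model == "simple") simple_type_term(per, cnt) else cnt * per
    }
  }
  total
}

#' @rdname entropy_state
#' @param state an `entropy_state()` object.
#' @param v vertex to move.
#' @param i proposed cluster label in `1..m`.
#' @export
delta_log_z <- function(state, v, i) {
  stopifnot(inherits(state, "hg_entropy_state"))
  i <- as.integer(i)
  a <- state$labels[v]
  if (i == a) return(0)
  # retype the edges incident to v
  new_counts <- state$counts
  touched <- character(0)
  for (e in state$inc[[v]]) {
    edge <- state$h$edges[[e]]
    lab <- state$labels[edge]
    old_key <- state$edge_key[[e]]
    lab[edge == v] <- i
    new_key <- paste(sort(lab), collapse = " ")
    if (!old_key %in% names(new_counts)) new_counts[old_key] <- 0 # defensive
    if (!new_key %in% names(new_counts)) new_counts[new_key] <- 0
    new_counts[old_key] <- new_counts[old_key] - 1
    new_counts[new_key] <- new_counts[new_key] + 1
    touched <- c(touched, old_key, new_key)
  }
  new_sizes <- state$sizes
  new_sizes[a] <- new_sizes[a] - 1L
  new_sizes[i] <- new_sizes[i] + 1L
  if (state$model == "degree_corrected") {
    # cluster sizes do not enter the stub count: only the touched types and
    # the two cluster degree sums change
    touched <- unique(touched)
    d_v <- state$h$degrees[v]
    delta <- lgamma(state$e_i[a] - d_v + 1) - lgamma(state$e_i[a] + 1) +
      lgamma(state$e_i[i] + d_v + 1) - lgamma(state$e_i[i] + 1)
    old_t <- stats::setNames(rep(0, length(touched)), touched)
    present <- intersect(touched, names(state$counts))
    old_t[present] <- state$counts[present]
    delta +
      type_table_log_z(touched, new_counts[touched], new_sizes, state$m, state$model) -
      type_table_log_z(touched, old_t, state$sizes, state$m, state$model)
  } else {
    # the size change of clusters a and i alters N_lambda for every type
    # that intersects them, so all realized types are re-termed (their
    # number is small and independent of |E|)
    old_counts <- state$counts
    all_keys <- names(new_counts)
    old_full <- stats::setNames(rep(0, length(all_keys)), all_keys)
    old_full[names(old_counts)] <- old_counts
    type_table_log_z(all_keys, new_counts, new_sizes, state$m, state$model) -
      type_table_log_z(all_keys, old_full, state$sizes, state$m, state$model)
  }
}
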