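#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions via the contingency
#' table: 1 for identical partitions (up to relabeling), about 0 for
#' independent ones.
#'
#' @param labels_a,labels_b label vectors of equal length (any label
#'   alphabet).
#' @return a number in `[-1, 1]`, invariant to permuting either label
#'   alphabet.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(length(labels_a), 2)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Spectral clustering baseline on a 2-uniform hypergraph
#'
#' Comparator, not a contribution: normalized-Laplacian spectral clustering
#' on the multiplicity-weighted adjacency matrix (parallel edges enter as
#' weights), with k-means on the row-normalized leading eigenvectors.
#' Isolated vertices are assigned to the largest recovered cluster.
#'
#' @param g a 2-uniform [hypergraph()] (e.g. a clique projection).
#' @param m number of clusters.
#' @param seed optional integer seed (k-means initialization).
#' @param nstart k-means restarts.
#' @return integer labels in `1..m`.
#' @export
spectral_baseline <- function(g, m, seed = NULL, nstart = 20L) {
  stopifnot(inherits(g, "hypergraph"))
  if (any(lengths(g$edges) != 2L)) stop("spectral baseline requires 2-uniform input")
  if (length(g$edges) == 0L) stop("spectral baseline requires a nonempty graph")
  if (!is.null(seed)) set.seed(seed)
  n <- g$n
  A <- matrix(0, n, n)
  for (e in g$edges) {
    if (e[1L] == e[2L]) next
    A[e[1L], e[2L]] <- A[e[1L], e[2L]] + 1
    A[e[2L], e[1L]] <- A[e[2L], e[1L]] + 1
  }
  deg <- rowSums(A)
  active <- which(deg > 0)
  dinv <- 1 / sqrt(deg[active])
  S <- A[active, active, drop = FALSE] * tcrossprod(dinv)
  U <- eigen(S, symmetric = TRUE)$vectors[, seq_len(m), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  km <- stats::kmeans(U / rn, centers = m, nstart = nstart, iter.max = 100L)
  labels <- integer(n)
  labels[active] <- km$cluster
  if (length(active) < n) {
    largest <- which.max(tabulate(km$cluster, m))
    labels[-active] <- largest
  }
  labels
}

#' ARI sweep over the planted-partition parameter grid
#'
#' For every `(p2, p3)` cell, generates `replicates` planted-partition
#' hypergraphs, clusters each with the best of `attempts` annealing runs
#' (or with the spectral baseline on a projection), and averages the ARI
#' against the planted labels.
#'
#' @inheritParams planted_partition
#' @inheritParams anneal
#' @param p2_grid,p3_grid numeric vectors of within-proportions in `[0, 1]`.
#' @param replicates hypergraphs generated per cell.
#' @param attempts independent annealing runs per hypergraph (best-of).
#' @param pipeline cluster the hypergraph natively, or its simple or
#'   multi-edge clique projection.
#' @param seed base seed; every cell/replicate derives its own seed.
#' @return a data frame of class `"hg_sweep"` with columns `p2`, `p3`,
#'   `mean_ari`; generation and optimization settings are kept in
#'   `attr(, "meta")`.
#' @export
heatmap_sweep <- function(p2_grid = seq(0, 1, length.out = 11),
                          p3_grid = seq(0, 1, length.out = 11),
                          n = 200L, replicates = 2L, attempts = 5L,
                          model = "degree_corrected",
                          pipeline = c("hypergraph", "simple_projection",
                                       "multiedge_projection"),
                          steps = 20000L, beta_rate = 1e-4, seed = 0L) {
  pipeline <- match.arg(pipeline)
  stopifnot(all(p2_grid >= 0 & p2_grid <= 1), all(p3_grid >= 0 & p3_grid <= 1))
  grid <- expand.grid(p2 = p2_grid, p3 = p3_grid, KEEP.OUT.ATTRS = FALSE)
  mean_ari <- numeric(nrow(grid))
  cell_seed <- as.numeric(seed)
  for (g in seq_len(nrow(grid))) {
    aris <- numeric(replicates)
    for (rep_i in seq_len(replicates)) {
      cell_seed <- (cell_seed + 1) %% .Machine$integer.max
      pp <- planted_partition(n, grid$p2[g], grid$p3[g],
                              seed = as.integer(cell_seed))
      target <- switch(pipeline,
                       hypergraph = pp$hypergraph,
                       simple_projection = simple_projection(pp$hypergraph),
                       multiedge_projection = multiedge_projection(pp$hypergraph))
      fit <- multi_run_anneal(target, m = 2L, model = model, runs = attempts,
                              steps = steps, beta_rate = beta_rate,
                              seed = as.integer(cell_seed))
      aris[rep_i] <- adjusted_rand_index(fit$best_labels, pp$labels)
    }
    mean_ari[g] <- mean(aris)
  }
  out <- cbind(grid, mean_ari = mean_ari)
  attr(out, "meta") <- list(n = n, replicates = replicates,
                            attempts = attempts, model = model,
                            pipeline = pipeline, steps = steps,
                            beta_rate = beta_rate, seed = seed)
  class(out) <- c("hg_sweep", class(out))
  out
}

#' Per-run entropy versus ARI records
#'
#' Runs `runs` independent annealing chains per model on one hypergraph and
#' records each run's best entropy together with the ARI of its best
#' assignment against the ground truth, enabling the entropy-vs-accuracy
#' inverse-correlation check.
#'
#' @inheritParams anneal
#' @param truth ground-truth labels for `h`.
#' @param runs independent runs per model.
#' @param models character vector of counting models to profile.
#' @return a data frame with columns `model`, `run`, `best_log_z`, `ari`
#'   (one row per run and model).
#' @export
entropy_vs_ari <- function(h, truth, runs = 50L, m = max(truth),
                           models = "degree_corrected",
                           steps = 20000L, beta_rate = 1e-4, seed = 0L) {
  recs <- vector("list", length(models) * runs)
  k <- 0L
  for (mod in models) {
    for (r in seq_len(runs)) {
      run_seed <- (as.numeric(seed) + k) %% .Machine$integer.max
      fit <- anneal(h, m = m, model = mod, steps = steps,
                    beta_rate = beta_rate, seed = as.integer(run_seed))
      k <- k + 1L
      recs[[k]] <- data.frame(model = mod, run = r,
                              best_log_z = fit$best_log_z,
                              ari = adjusted_rand_index(fit$best_labels, truth))
    }
  }
  do.call(rbind, recs)
}
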