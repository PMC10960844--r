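test_that("planted partition emits exact edge counts and balanced communities", {
  pp <- planted_partition(200, p2 = 0.8, p3 = 0.6, seed = 1)
  sizes <- lengths(pp$hypergraph$edges)
  expect_equal(sum(sizes == 2), 1000L) # exactly 5n 2-edges
  expect_equal(sum(sizes == 3), 667L)  # round(10n/3)
  expect_true(pp$hypergraph$is_simple)
  expect_equal(tabulate(pp$labels, 2), c(200L, 200L))
  # per-vertex mean 2-edge incidence is exactly 5 by construction
  two_edges <- pp$hypergraph$edges[sizes == 2]
  expect_equal(mean(tabulate(unlist(two_edges), 400)), 5)
})

test_that("boundary within-proportions pin the realized lambda-types", {
  pp1 <- planted_partition(30, 1, 1, seed = 2)
  cmp1 <- compress(pp1$hypergraph, pp1$labels, 2)
  expect_setequal(names(cmp1$e_lambda), c("1 1", "2 2", "1 1 1", "2 2 2"))

  pp0 <- planted_partition(30, 0, 0, seed = 2)
  cmp0 <- compress(pp0$hypergraph, pp0$labels, 2)
  expect_setequal(names(cmp0$e_lambda), c("1 2", "1 1 2", "1 2 2"))

  # within-edge counts split evenly between the two communities
  counts1 <- cmp1$e_lambda
  expect_lte(abs(counts1[["1 1"]] - counts1[["2 2"]]), 1L)
  expect_lte(abs(counts1[["1 1 1"]] - counts1[["2 2 2"]]), 1L)
  counts0 <- cmp0$e_lambda
  expect_lte(abs(counts0[["1 1 2"]] - counts0[["1 2 2"]]), 1L)
})

test_that("maximal-signal planted hypergraphs are recovered by annealing", {
  hits <- vapply(1:20, function(s) {
    pp <- planted_partition(25, 1, 1, seed = s)
    fit <- anneal(pp$hypergraph, 2, "degree_corrected", steps = 20000,
                  seed = s)
    adjusted_rand_index(fit$best_labels, pp$labels) == 1
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("dchsbm edge inclusion follows the Poisson thinning closed form", {
  N <- 30L
  set.seed(89)
  theta <- 1 / sample.int(8, N, replace = TRUE)
  omega_in <- 1; omega_out <- 0.1
  labels <- rep(1:2, each = 15)
  # fixed within and cross pairs; non-successor pairs cannot arise from
  # single-support replacement, so the Poisson thinning closed form is exact
  u <- 2L; v <- 4L; x <- 2L; y <- 17L
  p_within <- 1 - exp(-2 * theta[u] * theta[v] * omega_in)
  p_cross <- 1 - exp(-2 * theta[x] * theta[y] * omega_out)
  reps <- 600
  seen_w <- 0; seen_c <- 0
  for (r in seq_len(reps)) {
    g <- dchsbm(cluster_sizes = c(15L, 15L), omega_in = omega_in,
                omega_out = omega_out, theta = theta, seed = 1000 + r)
    keys <- vapply(g$hypergraph$edges, paste, "", collapse = " ")
    seen_w <- seen_w + (paste(u, v) %in% keys)
    seen_c <- seen_c + (paste(x, y) %in% keys)
  }
  expect_lt(abs(seen_w / reps - p_within),
            4 * sqrt(max(p_within * (1 - p_within), 1e-4) / reps))
  expect_lt(abs(seen_c / reps - p_cross),
            4 * sqrt(max(p_cross * (1 - p_cross), 1e-4) / reps))
})

test_that("dchsbm default instances land in the pilot count envelope", {
  g <- dchsbm(seed = 7)
  sizes <- lengths(g$hypergraph$edges)
  expect_gte(sum(sizes == 2), 40L)
  expect_lte(sum(sizes == 2), 320L)
  expect_gte(sum(sizes == 3), 400L)
  expect_lte(sum(sizes == 3), 3600L)
  expect_equal(g$hypergraph$n, 100L)
  # no parallel edges survive deduplication
  expect_false(anyDuplicated(vapply(g$hypergraph$edges, paste, "",
                                    collapse = " ")) > 0)
})

test_that("dchsbm degrees are heterogeneous but cluster-uninformative", {
  g <- dchsbm(seed = 11)
  d <- g$hypergraph$degrees
  expect_gte(mean(d[d >= stats::quantile(d, 0.9)]) /
               max(mean(d[d <= stats::quantile(d, 0.1)]), 1), 5)
  # similar degree mass in the two ground-truth clusters
  ratio <- sum(d[g$labels == 1]) / sum(d[g$labels == 2])
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
})

test_that("single-support edges are replaced by successor pairs", {
  # theta = 1 everywhere makes {v,v} and {v,v,v} draws near-certain
  g <- dchsbm(cluster_sizes = c(2L, 2L), omega_in = 6, omega_out = 0.5,
              theta = rep(1, 4), seed = 3)
  edges <- g$hypergraph$edges
  expect_true(all(vapply(edges, function(e) length(unique(e)) > 1L, TRUE)))
  # omega_out = 0 keeps every multi-vertex edge within one cluster
  g0 <- suppressWarnings(
    dchsbm(cluster_sizes = c(4L, 4L), omega_in = 6, omega_out = 0,
           theta = rep(1, 8), seed = 4))
  lab <- g0$labels
  mixed <- vapply(g0$hypergraph$edges, function(e)
    length(unique(lab[e])) > 1L, TRUE)
  # the only mixed edges permitted are successor-pair replacements across
  # the cluster boundary
  repl_ok <- vapply(g0$hypergraph$edges[mixed], function(e)
    length(e) == 2L && (e[2] - e[1] == 1L || (e[1] == 1L && e[2] == 8L)), TRUE)
  expect_true(all(repl_ok))
})

test_that("multiset edges can be collapsed on request", {
  g <- dchsbm(cluster_sizes = c(3L, 3L), omega_in = 6, omega_out = 0.5,
              theta = rep(1, 6), seed = 5, keep_multiset_edges = FALSE)
  expect_true(all(vapply(g$hypergraph$edges, anyDuplicated, 0L) == 0L))
})
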