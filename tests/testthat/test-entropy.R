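test_that("simple and multiset counts match frozen hand evaluations", {
  # one 2-edge in a 3-cluster: 3 simple hypergraphs share the compression
  h <- hypergraph(list(c(1, 2)), n = 3)
  expect_equal(log_z_simple(compress(h, c(1, 1, 1))), log(3))
  expect_equal(log_z_multiset(compress(h, c(1, 1, 1))), log(3))
  # sizes (2,1), one (1,1)-edge: {a,c} or {b,c}
  h2 <- hypergraph(list(c(1, 3)), n = 3)
  expect_equal(log_z_simple(compress(h2, c(1, 1, 2), m = 2)), log(2))
  # no edges: unique empty hypergraph
  he <- hypergraph(list(), n = 4)
  expect_equal(log_z_simple(compress(he, rep(1, 4), m = 1)), 0)
  expect_equal(log_z_multiset(compress(he, rep(1, 4), m = 1)), 0)
  # duplicated edge doubles the multiset contribution
  hd <- hypergraph(list(c(1, 2), c(1, 2)), n = 3)
  expect_equal(log_z_multiset(compress(hd, c(1, 1, 1))), 2 * log(3))
  # ... and overflows the simple count once the cluster admits only one
  # distinct edge of the type
  hd2 <- hypergraph(list(c(1, 2), c(1, 2)), n = 2)
  expect_error(log_z_simple(compress(hd2, c(1, 1))), "infeasible")
})

test_that("brute-force enumeration matches exp(log Z) on tiny instances", {
  set.seed(23)
  for (i in 1:8) {
    n <- sample(3:5, 1)
    h <- rand_hypergraph(n, sample(1:3, 1), max_size = 3, simple = TRUE)
    labels <- sample.int(2, n, replace = TRUE)
    cmp <- compress(h, labels, 2)
    expect_equal(brute_force_simple_count(h$edges, labels, n),
                 round(exp(log_z_simple(cmp))))
    expect_equal(brute_force_multiset_count(h$edges, labels, n),
                 round(exp(log_z_multiset(cmp))))
  }
})

test_that("degree-corrected count matches hand values and stub matching", {
  # one 2-edge, d = (1,1): unique stub pairing
  h <- hypergraph(list(c(1, 2)))
  expect_equal(log_z_degree_corrected(compress(h, c(1, 1), with_degrees = TRUE)), 0)
  # two singleton clusters, one (1,1)-edge: forced configuration
  expect_equal(log_z_degree_corrected(compress(h, c(1, 2), m = 2,
                                               with_degrees = TRUE)), 0)
  # two parallel 2-edges on d = (2,2): enumerated matchings of 4 stubs
  h2 <- hypergraph(list(c(1, 2), c(1, 2)))
  z <- exp(log_z_degree_corrected(compress(h2, c(1, 1), with_degrees = TRUE)))
  expect_equal(round(z), brute_force_pair_matchings(2)) # 3
  expect_error(log_z_degree_corrected(compress(h2, c(1, 1))), "degree")
})

test_that("factored stub count a(gamma)c(gamma) equals the closed form", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:12, 1)
    h <- rand_hypergraph(n, sample(3:9, 1), max_size = 4)
    m <- sample(2:4, 1)
    cmp <- compress(h, sample.int(m, n, replace = TRUE), m, with_degrees = TRUE)
    expect_equal(hypermi:::log_z_dc_factored(cmp), log_z_degree_corrected(cmp),
                 tolerance = 1e-9)
  }
})

test_that("graph module-matrix count equals the simple count on 2-uniform input", {
  expect_equal(log_z_graph(matrix(1L, 1, 1), 3), log(3))
  expect_equal(log_z_graph(matrix(0L, 2, 2), c(3, 4)), 0)
  set.seed(37)
  for (i in 1:4) {
    n <- 6
    h <- rand_hypergraph(n, 7, max_size = 2, simple = TRUE)
    for (code in 0:(3^n - 1)) {
      labels <- (code %/% 3^(0:(n - 1))) %% 3 + 1
      expect_equal(log_z(h, labels, 3, "graph"),
                   log_z_simple(compress(h, labels, 3)), tolerance = 1e-9)
    }
  }
  # and on a larger sampled assignment space
  h8 <- rand_hypergraph(8, 10, max_size = 2, simple = TRUE)
  for (i in 1:50) {
    labels <- sample.int(3, 8, replace = TRUE)
    expect_equal(log_z(h8, labels, 3, "graph"),
                 log_z_simple(compress(h8, labels, 3)), tolerance = 1e-9)
  }
})

test_that("simple, multiset and graph entropies are nonnegative when feasible", {
  set.seed(43)
  for (i in 1:20) {
    h <- rand_hypergraph(8, 6, simple = TRUE)
    labels <- sample.int(3, 8, replace = TRUE)
    expect_gte(log_z_simple(compress(h, labels, 3)), 0)
    expect_gte(log_z_multiset(compress(h, labels, 3)), 0)
  }
})

test_that("single-vertex deltas agree with full recomputation", {
  set.seed(47)
  models <- c("simple", "multiset", "degree_corrected")
  for (mod in models) {
    checked <- 0L
    while (checked < 120L) {
      h <- rand_hypergraph(9, 8, max_size = 3, simple = mod == "simple")
      m <- 3L
      labels <- sample.int(m, h$n, replace = TRUE)
      st <- entropy_state(h, labels, m, mod)
      base <- log_z(h, labels, m, mod)
      for (k in 1:10) {
        v <- sample.int(h$n, 1)
        i <- sample.int(m, 1)
        labels2 <- labels
        labels2[v] <- i
        expect_equal(delta_log_z(st, v, i),
                     log_z(h, labels2, m, mod) - base, tolerance = 1e-9)
        checked <- checked + 1L
      }
    }
  }
})

test_that("moving an isolated vertex is entropy-neutral under degree correction", {
  h <- hypergraph(list(c(1, 2), c(2, 3)), n = 5) # vertices 4,5 isolated
  labels <- c(1L, 1L, 2L, 1L, 2L)
  st <- entropy_state(h, labels, 2, "degree_corrected")
  expect_equal(delta_log_z(st, 4, 2), 0)
  expect_equal(delta_log_z(st, 5, 1), 0)
  expect_equal(delta_log_z(st, 1, 1), 0) # self-move
})

test_that("degree-corrected entropy ignores within-cluster degree placement", {
  set.seed(53)
  for (i in 1:15) {
    h <- rand_hypergraph(10, 9)
    labels <- sample.int(3, 10, replace = TRUE)
    base <- log_z(h, labels, 3, "degree_corrected")
    # swap all roles of two same-cluster vertices: within-cluster degree
    # permutation with identical e_i and e_lambda
    cl <- sample(unique(labels), 1)
    pair <- sample(which(labels == cl), 2)
    perm <- seq_len(10)
    perm[pair] <- rev(pair)
    h2 <- hypergraph(lapply(h$edges, function(e) perm[e]), n = 10)
    expect_equal(log_z(h2, labels, 3, "degree_corrected"), base,
                 tolerance = 1e-9)
  }
})
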