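# Brute-force counting oracles and small random-instance builders.  The
# oracles enumerate explicitly; they never reuse the package's closed-form
# counts.

# all distinct-vertex candidate edges of a given size on n vertices
candidate_edges <- function(n, size) {
  cm <- utils::combn(n, size)
  lapply(seq_len(ncol(cm)), function(j) cm[, j])
}

type_of <- function(edge, labels) paste(sort(labels[edge]), collapse = " ")

# number of SIMPLE hypergraphs whose compression under `labels` matches the
# compression of `edges`: enumerate subsets of all candidate edges and
# compare type histograms
brute_force_simple_count <- function(edges, labels, n) {
  sizes <- sort(unique(lengths(edges)))
  cands <- unlist(lapply(sizes, candidate_edges, n = n), recursive = FALSE)
  target <- sort(vapply(edges, type_of, "", labels = labels))
  k <- length(edges)
  hits <- 0L
  picks <- utils::combn(length(cands), k)
  for (j in seq_len(ncol(picks))) {
    got <- sort(vapply(cands[picks[, j]], type_of, "", labels = labels))
    if (identical(got, target)) hits <- hits + 1L
  }
  hits
}

# number of labeled multi-hypergraph edge sequences compatible with the
# compression: each edge slot independently ranges over the candidate edges
# of its lambda-type (candidates counted by enumeration)
brute_force_multiset_count <- function(edges, labels, n) {
  out <- 1
  for (e in edges) {
    cands <- candidate_edges(n, length(e))
    tt <- type_of(e, labels)
    out <- out * sum(vapply(cands, type_of, "", labels = labels) == tt)
  }
  out
}

# number of ways to group 2k labeled stubs into k unordered pairs
# (stub-matching count for k parallel 2-edges within one cluster)
brute_force_pair_matchings <- function(k) {
  count <- function(stubs) {
    if (length(stubs) == 0L) return(1L)
    first <- stubs[1L]
    rest <- stubs[-1L]
    sum(vapply(seq_along(rest), function(j)
      count(rest[-j]), 0L))
  }
  count(seq_len(2L * k))
}

# small random multi-hypergraph (distinct-vertex edges, duplicates allowed
# unless simple = TRUE)
rand_hypergraph <- function(n, n_edges, max_size = 3L, simple = FALSE,
                            cover = FALSE) {
  ks <- 2:max_size
  repeat {
    edges <- lapply(seq_len(n_edges), function(i) {
      k <- if (length(ks) == 1L) ks else sample(ks, 1L)
      sort(sample.int(n, k))
    })
    if (simple && anyDuplicated(vapply(edges, paste, "", collapse = " ")))
      next
    if (cover && length(unique(unlist(edges))) < n) next
    return(hypergraph(edges, n = n))
  }
}
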