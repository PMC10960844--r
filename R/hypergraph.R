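#' Construct a hypergraph
#'
#' A hypergraph is a vertex set together with a list of hyperedges, each of
#' which is a multiset of vertices (repeated vertices within an edge are
#' allowed and are counted with multiplicity in the vertex degrees).
#'
#' @param edges list of integer vectors; each vector lists the (1-based)
#'   vertex indices of one hyperedge, repeats allowed.  Each edge is stored
#'   sorted, so that multiset equality of edges is positional equality.
#' @param n number of vertices.  Defaults to the largest index appearing in
#'   `edges`; supply explicitly if isolated vertices exist.
#' @param vertex_names optional character vector of external vertex
#'   identifiers, length `n`.  Defaults to `as.character(seq_len(n))`.
#'
#' @return An object of class `"hypergraph"`: a list with elements `edges`
#'   (sorted integer vectors), `n`, `degrees` (`d[v]` = number of edge slots
#'   occupied by `v`, counted with multiplicity), `is_simple` (`TRUE` iff no
#'   edge repeats a vertex and no two edges are equal as multisets) and
#'   `vertex_names`.
#' @export
#' @examples
#' h <- hypergraph(list(c(1, 2), c(1, 2, 3)))
#' h$degrees         # 2 2 1
#' h$is_simple       # TRUE
hypergraph <- function(edges, n = NULL, vertex_names = NULL) {
  if (!is.list(edges)) stop("`edges` must be a list of integer vectors")
  edges <- lapply(edges, function(e) {
    e <- as.integer(e)
    if (length(e) < 1L) stop("every edge must have size >= 1")
    if (anyNA(e) || any(e < 1L)) stop("vertex indices must be positive integers")
    sort(e)
  })
  max_idx <- if (length(edges)) max(vapply(edges, max, 1L)) else 0L
  if (is.null(n)) n <- if (!is.null(vertex_names)) length(vertex_names) else max_idx
  n <- as.integer(n)
  if (max_idx > n) stop("edge refers to vertex ", max_idx, " but n = ", n)
  if (is.null(vertex_names)) vertex_names <- as.character(seq_len(n))
  if (length(vertex_names) != n) stop("`vertex_names` must have length n")
  if (anyDuplicated(vertex_names)) stop("vertex names must be unique")
  degrees <- tabulate(as.integer(unlist(edges)), nbins = n)
  no_repeats <- !any(vapply(edges, anyDuplicated, 0L) > 0L)
  keys <- edge_keys(edges)
  structure(
    list(edges = edges, n = n, degrees = degrees,
         is_simple = no_repeats && !anyDuplicated(keys),
         vertex_names = vertex_names),
    class = "hypergraph")
}

# canonical text key of each (sorted) edge; multiset equality <=> key equality
edge_keys <- function(edges) {
  vapply(edges, paste, "", collapse = " ")
}

#' @export
print.hypergraph <- function(x, ...) {
  sizes <- lengths(x$edges)
  cat("hypergraph: ", x$n, " vertices, ", length(x$edges), " edges",
      if (x$is_simple) " (simple)" else " (non-simple)", "\n", sep = "")
  if (length(sizes)) {
    tab <- table(sizes)
    cat("edge sizes: ",
        paste0(names(tab), "-edges: ", as.integer(tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read a hyperedge list from a text file
#'
#' One hyperedge per line; vertex tokens separated by runs of whitespace (or
#' by commas for `dialect = "comma"`).  Lines starting with `#` and blank
#' lines are ignored.  Tokens are mapped to dense vertex indices in order of
#' first appearance; a token repeated on one line is kept as a multiset
#' multiplicity.
#'
#' @param path file path or connection.
#' @param dialect token separator convention.
#' @return a [hypergraph()].
#' @export
read_hyperedges <- function(path, dialect = c("whitespace", "comma")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("no edges in ", paste(path, collapse = ""))
  toks <- if (dialect == "whitespace") {
    strsplit(trimws(lines), "\\s+")
  } else {
    lapply(strsplit(lines, ",", fixed = TRUE), trimws)
  }
  bad <- which(vapply(toks, function(x) length(x) == 0L || any(x == ""), TRUE))
  if (length(bad)) stop("malformed edge on line ", lineno[bad[1L]])
  all_tok <- unlist(toks)
  vertex_names <- unique(all_tok)
  idx <- split(match(all_tok, vertex_names), rep(seq_along(toks), lengths(toks)))
  hypergraph(unname(idx), n = length(vertex_names), vertex_names = vertex_names)
}

#' Write a hypergraph as a hyperedge-list text file
#'
#' @param h a [hypergraph()].
#' @param path file path or connection.
#' @param dialect token separator convention.
#' @return `path`, invisibly.
#' @export
write_hyperedges <- function(h, path, dialect = c("whitespace", "comma")) {
  stopifnot(inherits(h, "hypergraph"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "whitespace") " " else ","
  lines <- vapply(h$edges, function(e) paste(h$vertex_names[e], collapse = sep), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write vertex partitions
#'
#' Partitions are stored as two-column tab-separated text
#' (`vertex<TAB>cluster`), one vertex per line, with an optional header.
#' `read_partition` returns integer labels ordered as `vertex_names`;
#' labels are preserved verbatim, so `read_partition(write_partition(...))`
#' is the identity.
#'
#' @param labels integer cluster labels, one per vertex.
#' @param vertex_names character vector of unique vertex tokens, parallel to
#'   `labels`; for reading, the full vertex set that must be covered.
#' @param path file path or connection.
#' @return `write_partition` returns `path` invisibly; `read_partition`
#'   returns a named integer vector of labels in `vertex_names` order.
#' @export
write_partition <- function(labels, vertex_names, path) {
  if (length(labels) != length(vertex_names))
    stop("`labels` and `vertex_names` must have equal length")
  if (anyDuplicated(vertex_names)) stop("vertex names must be unique")
  writeLines(paste(vertex_names, as.integer(labels), sep = "\t"), path)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path, vertex_names) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("partition file must have two tab-separated columns")
  tok <- vapply(parts, `[[`, "", 1L)
  lab <- vapply(parts, `[[`, "", 2L)
  # optional header: first row whose label does not parse as an integer
  if (length(lab) && is.na(suppressWarnings(as.integer(lab[1L])))) {
    tok <- tok[-1L]; lab <- lab[-1L]
  }
  labi <- suppressWarnings(as.integer(lab))
  if (anyNA(labi)) stop("non-integer cluster label in partition file")
  if (anyDuplicated(tok)) stop("duplicate vertex token: ", tok[duplicated(tok)][1L])
  unknown <- setdiff(tok, vertex_names)
  if (length(unknown)) stop("unknown vertex token: ", unknown[1L])
  missing <- setdiff(vertex_names, tok)
  if (length(missing)) stop("partition does not label vertex: ", missing[1L])
  out <- labi[match(vertex_names, tok)]
  names(out) <- vertex_names
  out
}
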