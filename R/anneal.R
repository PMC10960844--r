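#' Metropolis acceptance probability
#'
#' @param delta entropy difference `log Z(c') - log Z(c)` of the proposed
#'   move, in nats.
#' @param beta inverse temperature, nonnegative.
#' @return `min(1, exp(-beta * delta))`; 1 whenever `delta <= 0`.
#' @export
accept_probability <- function(delta, beta) {
  stopifnot(beta >= 0)
  pmin(1, exp(-beta * delta))
}

#' Uniform single-vertex move proposal
#'
#' Draws a vertex and a candidate label uniformly from the `n * m` grid.
#' The candidate may equal the vertex's current label, so about `1/m` of
#' proposals leave the clustering unchanged.
#'
#' @param n number of vertices.
#' @param m label budget.
#' @return integer vector `c(v, i)`.
#' @export
propose_move <- function(n, m) {
  c(sample.int(n, 1L), sample.int(m, 1L))
}

#' Cluster a hypergraph by simulated annealing
#'
#' Minimizes the compression entropy `log Z` over cluster assignments with a
#' Metropolis-Hastings random walk: starting from a uniformly random
#' assignment, at step `t` a vertex/label pair is proposed uniformly and
#' accepted with probability `min(1, exp(-beta(t) * delta))`, where
#' `beta(t) = (t + 1) * beta_rate` and `delta` is the entropy change.  The
#' lowest-entropy assignment seen anywhere along the walk is returned.
#'
#' @inheritParams log_z
#' @param m label budget (empty clusters are permitted).
#' @param steps number of Metropolis steps.
#' @param beta_rate slope of the linear inverse-temperature schedule
#'   `beta(t) = (t + 1) * beta_rate` (entropy in nats).
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   so repeated calls are bit-identical.
#' @param init optional initial assignment (defaults to i.i.d. uniform
#'   labels).
#' @param record_trace record the per-step current and best entropy.
#' @return An object of class `"hg_anneal"`: `best_labels`, `best_log_z`,
#'   `final_labels`, `final_log_z`, `accepted` (number of accepted
#'   proposals, self-label proposals included), `model`, `m`, `steps`,
#'   `beta_rate`, and (when requested) `trace`, a data frame with columns
#'   `step`, `log_z`, `best_log_z`.
#' @details The simple model refuses hypergraphs with parallel edges (their
#'   compressions are not feasible simple-hypergraph counts).  Edges with
#'   repeated vertices are accepted by every model; under the simple count
#'   any assignment rendering the type counts infeasible is treated as
#'   having infinite entropy and is never accepted.  The `"graph"` model
#'   requires 2-uniform input and coincides with the simple count there.
#' @export
anneal <- function(h, m, model = c("degree_corrected", "simple", "multiset", "graph"),
                   steps = 20000L, beta_rate = 1e-4, seed = NULL,
                   init = NULL, record_trace = FALSE) {
  stopifnot(inherits(h, "hypergraph"), m >= 1, steps >= 1, beta_rate > 0)
  model <- match.arg(model)
  run_model <- model
  if (model == "graph") {
    if (any(lengths(h$edges) != 2L))
      stop("graph model requires a 2-uniform hypergraph")
    run_model <- "simple"
  }
  if (run_model == "simple" && anyDuplicated(edge_keys(h$edges)))
    stop("simple model requires a hypergraph without parallel edges")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- sample.int(m, h$n, replace = TRUE)
  init <- as.integer(init)
  stopifnot(length(init) == h$n, all(init >= 1L), all(init <= m))
  code <- match(run_model, c("simple", "multiset", "degree_corrected")) - 1L
  edges0 <- lapply(h$edges, function(e) e - 1L)
  res <- .anneal_cpp(edges0, h$n, as.integer(m), code, as.integer(steps),
                     beta_rate, init - 1L, isTRUE(record_trace))
  out <- list(best_labels = res$best + 1L, best_log_z = res$best_log_z,
              final_labels = res$final + 1L, final_log_z = res$final_log_z,
              accepted = res$accepted, model = model, m = as.integer(m),
              steps = as.integer(steps), beta_rate = beta_rate)
  if (isTRUE(record_trace)) {
    out$trace <- data.frame(step = seq_len(steps),
                            log_z = res$trace_current,
                            best_log_z = res$trace_best)
  }
  class(out) <- "hg_anneal"
  out
}

#' @export
print.hg_anneal <- function(x, ...) {
  cat("simulated annealing (", x$model, " model, m = ", x$m, ")\n", sep = "")
  cat("best entropy: ", format(x$best_log_z), " nats (",
      format(x$best_log_z / log(2)), " bits)\n", sep = "")
  cat("accepted ", x$accepted, " of ", x$steps, " proposals\n", sep = "")
  invisible(x)
}

#' Best-of-R independent annealing runs
#'
#' Executes `runs` independent [anneal()] calls with per-run seeds derived
#' deterministically from `seed` (run `r` uses `seed + r - 1`) and returns
#' the run with the lowest best entropy; ties go to the earliest run.
#'
#' @inheritParams anneal
#' @param runs number of independent runs.
#' @param seed base seed for the deterministic per-run seed sequence.
#' @return the winning run's `"hg_anneal"` object, with extra fields `runs`
#'   (count), `run_best_log_z` (per-run best entropies) and `winning_run`.
#' @export
multi_run_anneal <- function(h, m, model = c("degree_corrected", "simple",
                                             "multiset", "graph"),
                             runs = 50L, steps = 20000L, beta_rate = 1e-4,
                             seed = 0L, record_trace = FALSE) {
  stopifnot(runs >= 1)
  model <- match.arg(model)
  best <- NULL
  per_run <- numeric(runs)
  win <- 1L
  for (r in seq_len(runs)) {
    run_seed <- (as.numeric(seed) + r - 1) %% .Machine$integer.max
    res <- anneal(h, m, model, steps = steps, beta_rate = beta_rate,
                  seed = as.integer(run_seed), record_trace = record_trace)
    per_run[r] <- res$best_log_z
    if (is.null(best) || res$best_log_z < best$best_log_z) {
      best <- res
      win <- r
    }
  }
  best$runs <- as.integer(runs)
  best$run_best_log_z <- per_run
  best$winning_run <- win
  best
}
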