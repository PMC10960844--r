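#' Description length of a clustered hypergraph
#'
#' Total description length in bits: the partition/model cost plus the
#' data-given-model cost,
#' \deqn{L = n \log_2 m + \sum_{k=2}^{k^*} \binom{m+k-1}{k} \log_2 \ell_k
#'       + \log_2 Z(\gamma),}
#' where \eqn{\ell_k} is the number of size-`k` hyperedges and \eqn{k^*}
#' the largest edge size.  Terms with \eqn{\ell_k \le 1} contribute 0 and
#' no smoothing is applied; size-1 edges contribute nothing to the model
#' cost but do enter `log Z`.
#'
#' @inheritParams log_z
#' @return description length in bits.
#' @export
description_length <- function(h, labels, m = max(labels),
                               model = c("degree_corrected", "simple",
                                         "multiset", "graph")) {
  model <- match.arg(model)
  if (m < 1) stop("m must be at least 1")
  sizes <- lengths(h$edges)
  model_cost <- h$n * log2(m)
  if (length(sizes)) {
    for (k in 2:max(2L, max(sizes))) {
      lk <- sum(sizes == k)
      if (lk > 1L) model_cost <- model_cost + choose(m + k - 1, k) * log2(lk)
    }
  }
  model_cost + log_z(h, labels, m, model) / log(2)
}

#' Select the number of clusters by minimum description length
#'
#' For each candidate `m`, runs `replicates` independent annealing chains,
#' computes the description length of each chain's best assignment, and
#' selects the `m` with the lowest mean description length (ties go to the
#' smaller `m`).  This coding scheme is known to frequently underestimate
#' the number of planted clusters; treat the selection as a parsimony
#' counterweight, not ground truth.
#'
#' @inheritParams anneal
#' @param m_range integer vector of candidate cluster counts.
#' @param replicates independent clusterings per candidate `m`.
#' @param seed base seed; replicate seeds are derived deterministically.
#' @return a data frame of class `"hg_mdl_report"` with one row per `m`
#'   (columns `m`, `mean_dl`, `sd_dl`, `min_dl`, in bits) and the chosen
#'   `m` in `attr(, "selected_m")`.
#' @export
select_m <- function(h, m_range, replicates = 10L,
                     model = c("degree_corrected", "simple", "multiset",
                               "graph"),
                     steps = 20000L, beta_rate = 1e-4, seed = 0L) {
  model <- match.arg(model)
  m_range <- sort(unique(as.integer(m_range)))
  stopifnot(length(m_range) >= 1, all(m_range >= 1), replicates >= 1)
  rows <- vector("list", length(m_range))
  k <- 0
  for (idx in seq_along(m_range)) {
    m <- m_range[idx]
    dls <- numeric(replicates)
    for (r in seq_len(replicates)) {
      run_seed <- (as.numeric(seed) + k) %% .Machine$integer.max
      k <- k + 1
      fit <- anneal(h, m = m, model = model, steps = steps,
                    beta_rate = beta_rate, seed = as.integer(run_seed))
      dls[r] <- description_length(h, fit$best_labels, m, model)
    }
    rows[[idx]] <- data.frame(m = m, mean_dl = mean(dls),
                              sd_dl = stats::sd(dls), min_dl = min(dls))
  }
  out <- do.call(rbind, rows)
  attr(out, "selected_m") <- out$m[which.min(out$mean_dl)]
  attr(out, "meta") <- list(replicates = replicates, model = model,
                            steps = steps, beta_rate = beta_rate, seed = seed)
  class(out) <- c("hg_mdl_report", class(out))
  out
}

#' @export
print.hg_mdl_report <- function(x, ...) {
  cat("minimum description length report (bits)\n")
  print.data.frame(x, row.names = FALSE, ...)
  cat("selected m* =", attr(x, "selected_m"), "\n")
  invisible(x)
}
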