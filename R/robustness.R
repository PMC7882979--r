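#' Network robustness under subsampling
#'
#' Asks whether the observed number of events is enough to pin down network
#' structure: for each sample size on `grid`, networks are repeatedly
#' rebuilt from random subsets of the events and their dyadic weight vector
#' is rank-correlated with the complete network's (all unordered roster
#' pairs, zero-weight dyads included, ties mid-ranked). The replicates
#' provide the per-size mean and percentile 95% confidence interval.
#'
#' By default events are drawn without replacement, so a sample size equal
#' to the full event count reproduces the complete network and the curve's
#' endpoint is exactly 1; set `replace = TRUE` for a classical bootstrap of
#' events instead. The default grid of 32 sizes runs from 15 events to 170
#' in steps of 5.
#'
#' @param parties List of per-event ID vectors ([gambit_party()]).
#' @param roster Network roster.
#' @param grid Increasing vector of sample sizes.
#' @param n_replicates Replicates per size (default 1000).
#' @param seed Optional integer seed.
#' @param replace Draw events with replacement.
#' @return A `"robustness_curve"` data frame with columns `n`, `mean`,
#'   `ci_low`, `ci_high`.
#' @export
robustness_curve <- function(parties, roster, grid = seq(15L, 170L, 5L),
                             n_replicates = 1000L, seed = NULL,
                             replace = FALSE) {
  stopifnot(length(roster) >= 3L, all(diff(grid) > 0))
  ne <- length(parties)
  if (max(grid) > ne) {
    stop("grid size ", max(grid), " exceeds event count ", ne,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  # event-incidence matrix once; per-replicate SRI is then one crossproduct
  inc <- vapply(parties, function(p) roster %in% p,
                logical(length(roster)))
  storage.mode(inc) <- "double"
  lower <- lower.tri(diag(length(roster)))
  sri_dyads <- function(cols) {
    m <- inc[, cols, drop = FALSE]
    x <- tcrossprod(m)
    npr <- rowSums(m)
    denom <- outer(npr, npr, "+") - x
    w <- ifelse(denom > 0, x / denom, 0)
    w[lower]
  }
  full <- sri_dyads(seq_len(ne))
  rows <- lapply(grid, function(sz) {
    r <- vapply(seq_len(n_replicates), function(b) {
      est <- sri_dyads(sample.int(ne, sz, replace = replace))
      if (stats::sd(est) == 0 || stats::sd(full) == 0) return(NA_real_)
      stats::cor(est, full, method = "spearman")
    }, 1)
    r <- r[!is.na(r)]
    ci <- if (length(r)) stats::quantile(r, c(0.025, 0.975), names = FALSE,
                                         type = 7) else c(NA, NA)
    data.frame(n = sz, mean = mean(r), ci_low = ci[1L], ci_high = ci[2L])
  })
  out <- do.call(rbind, rows)
  attr(out, "n_replicates") <- as.integer(n_replicates)
  attr(out, "seed") <- seed
  class(out) <- c("robustness_curve", "data.frame")
  out
}

#' Smallest sample size whose mean correlation is near the final one
#'
#' A plateau criterion for reading robustness curves: the smallest grid size
#' whose mean rank correlation lies within `tol` of the mean at the largest
#' size, indicating that further sampling buys only marginal improvement.
#'
#' @param curve A `"robustness_curve"`.
#' @param tol Closeness tolerance on the mean correlation (default 0.02).
#' @return Sample size (scalar).
#' @export
plateau_size <- function(curve, tol = 0.02) {
  final <- curve$mean[nrow(curve)]
  curve$n[which(curve$mean >= final - tol)[1L]]
}
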