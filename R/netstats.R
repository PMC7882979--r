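#' Node strength
#'
#' Sum of a node's edge weights (the weighted analogue of degree).
#'
#' @param m Symmetric non-negative weight matrix.
#' @param node Optional node name or index; all nodes when `NULL`.
#' @return Named numeric vector (or scalar for a single node).
#' @export
node_strength <- function(m, node = NULL) {
  s <- rowSums(m)
  if (is.null(node)) return(s)
  if (is.character(node) && !node %in% rownames(m)) {
    stop("unknown node: ", node, call. = FALSE)
  }
  s[[node]]
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the weight matrix, taken non-negative and scaled
#' so the maximum is 1. On disconnected graphs it is computed on the full
#' matrix, so the dominant component carries the mass. An all-zero matrix
#' yields all-zero centralities with a warning.
#'
#' @param m Symmetric non-negative weight matrix.
#' @return Named numeric vector in `[0, 1]`.
#' @export
eigenvector_centrality <- function(m) {
  stopifnot(isSymmetric(unclass(m)), all(m >= 0))
  if (all(m == 0)) {
    warning("all-zero network: centralities undefined, returning zeros")
    return(stats::setNames(rep(0, nrow(m)), rownames(m)))
  }
  e <- eigen(unclass(m), symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)                       # Perron vector; clip fp dust
  stats::setNames(v / max(v), rownames(m))
}

#' Weighted modularity of a partition
#'
#' Q = (1 / 2W) * sum_ij (A_ij - s_i s_j / 2W) delta(c_i, c_j), with s the
#' node strengths and W the total edge weight. The one-community partition
#' scores exactly zero.
#'
#' @param m Symmetric non-negative weight matrix.
#' @param membership Integer community labels covering every node.
#' @return Modularity Q.
#' @export
modularity_q <- function(m, membership) {
  stopifnot(length(membership) == nrow(m))
  W2 <- sum(m)                          # 2W: matrix counts each edge twice
  if (W2 == 0) stop("modularity undefined for an empty network",
                    call. = FALSE)
  s <- rowSums(m)
  B <- unclass(m) - outer(s, s) / W2
  same <- outer(membership, membership, "==")
  sum(B[same]) / W2
}

#' Community detection by recursive leading-eigenvector bisection
#'
#' Newman's spectral method on the weighted modularity matrix
#' B_ij = A_ij - s_i s_j / 2W: the current group is split by the sign of the
#' leading eigenvector of its generalized modularity matrix, components
#' exactly at zero going to the positive block. Recursion continues while
#' the leading eigenvalue exceeds `tol` and the split strictly increases Q;
#' no Kernighan-Lin refinement is applied, keeping the procedure
#' deterministic and directly checkable against exhaustive modularity
#' maximization on small graphs.
#'
#' @param m Symmetric non-negative weight matrix (an `"assoc_matrix"` or any
#'   plain matrix).
#' @param tol Spectral stop tolerance on the leading eigenvalue.
#' @return A `"network_partition"`: list with `membership` (named integer
#'   labels, contiguous from 0), `n_communities`, and `modularity`.
#' @export
leading_eigenvector_communities <- function(m, tol = 1e-10) {
  stopifnot(nrow(m) >= 1L, isSymmetric(unclass(m)), all(m >= 0))
  A <- unclass(m)
  n <- nrow(A)
  W2 <- sum(A)
  membership <- rep(0L, n)
  if (W2 > 0 && n > 1L) {
    s <- rowSums(A)
    B <- A - outer(s, s) / W2
    q_of <- function(memb) {
      sum(B[outer(memb, memb, "==")]) / W2
    }
    groups <- list(seq_len(n))
    next_label <- 0L
    membership <- rep(NA_integer_, n)
    while (length(groups)) {
      g <- groups[[1L]]
      groups <- groups[-1L]
      split_done <- FALSE
      if (length(g) > 1L) {
        # generalized modularity matrix for the subgraph
        Bg <- B[g, g, drop = FALSE]
        diag(Bg) <- diag(Bg) - rowSums(B[g, g, drop = FALSE])
        e <- eigen(Bg, symmetric = TRUE)
        lead <- which.max(e$values)
        if (e$values[lead] > tol) {
          v <- e$vectors[, lead]
          pos <- v >= 0                 # zeros join the positive block
          if (any(pos) && any(!pos)) {
            trial <- membership
            trial[g[pos]] <- -1L
            trial[g[!pos]] <- -2L
            # accept only if the split increases global Q
            base <- membership
            base[g] <- -1L
            fill <- function(x) { x[is.na(x)] <- -3L; x }
            if (q_of(fill(trial)) > q_of(fill(base)) + 1e-12) {
              groups <- c(groups, list(g[pos]), list(g[!pos]))
              split_done <- TRUE
            }
          }
        }
      }
      if (!split_done) {
        membership[g] <- next_label
        next_label <- next_label + 1L
      }
    }
  }
  names(membership) <- rownames(m)
  structure(list(membership = membership,
                 n_communities = length(unique(membership)),
                 modularity = if (W2 > 0) modularity_q(m, membership) else 0),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat("network partition:", x$n_communities, "communities, Q =",
      format(x$modularity, digits = 4), "\n")
  invisible(x)
}

# best label alignment between two partitions by maximum total overlap;
# exhaustive over permutations of the smaller label set (community counts
# here are single digits)
.align_overlap <- function(la, lb) {
  ua <- unique(la); ub <- unique(lb)
  if (length(ua) > length(ub)) return(.align_overlap(lb, la))
  ov <- table(factor(la, ua), factor(lb, ub))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- 0L
  for (p in perms(seq_along(ub))) {
    sel <- p[seq_along(ua)]
    best <- max(best, sum(ov[cbind(seq_along(ua), sel)]))
  }
  best
}

#' Co-membership agreement between two partitions
#'
#' Community labels of the two partitions are aligned by the
#' maximum-overlap assignment over label permutations; agreement is the
#' share of shared-roster individuals whose aligned labels match, reported
#' as a half-up-rounded integer percent.
#'
#' @param partition_a,partition_b `"network_partition"`s or named membership
#'   vectors.
#' @param roster Individuals to compare; defaults to the intersection of the
#'   two name sets.
#' @return List with `pct_same` (integer percent), `n_same`,
#'   `n_mismatched`, `n`.
#' @export
membership_agreement <- function(partition_a, partition_b, roster = NULL) {
  memb <- function(p) if (inherits(p, "network_partition")) p$membership else p
  a <- memb(partition_a); b <- memb(partition_b)
  if (is.null(roster)) roster <- intersect(names(a), names(b))
  if (!length(roster)) stop("partitions share no individuals", call. = FALSE)
  if (!all(roster %in% names(a)) || !all(roster %in% names(b))) {
    stop("both partitions must cover the shared roster", call. = FALSE)
  }
  n_same <- .align_overlap(a[roster], b[roster])
  list(pct_same = pct_round(100 * n_same / length(roster)),
       n_same = as.integer(n_same),
       n_mismatched = length(roster) - as.integer(n_same),
       n = length(roster))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged), as used to compare
#' individual network positions and dyadic structure across networks. A
#' constant vector makes the correlation undefined and returns `NA` with a
#' warning.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}
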