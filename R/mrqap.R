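# dyadic vectorization: strictly-lower-triangle of a symmetric matrix
.dyads <- function(m) unclass(m)[lower.tri(m)]

# rebuild a symmetric matrix (zero diagonal) from a dyad vector
.undyads <- function(v, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m + t(m)
}

# OLS on a design with intercept; returns coefficients, t stats, R2.
# Zero residual variance (perfect fit) caps |t| at .t_cap so permutation
# comparisons stay well-defined.
.t_cap <- 1e12
.ols_t <- function(X, y) {
  qr_ <- qr(X)
  beta <- qr.coef(qr_, y)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(pmax(diag(XtXinv) * s2, 0))
  tval <- ifelse(se > 0, beta / se, sign(beta) * .t_cap)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 1
  list(coef = as.vector(beta), t = as.vector(tval), r2 = r2)
}

#' MRQAP with double semi-partialling
#'
#' Regresses the dyads of one association matrix on those of one or more
#' predictor matrices and assesses significance with the double
#' semi-partialling node-permutation scheme of Dekker, Krackhardt and
#' Snijders (2007): each predictor is residualized on the remaining
#' predictors at the matrix level, the residual matrix has its rows and
#' columns jointly permuted by a random node permutation, the regression is
#' refit with the permuted residual in that predictor's place, and the
#' permuted |t| statistics form the reference distribution. The pivotal
#' t-statistic makes the test robust to collinearity among predictors and
#' network autocorrelation.
#'
#' All matrices must be symmetric with a shared roster; the strictly lower
#' triangle supplies the n(n-1)/2 dyads and the diagonal is ignored.
#' P-values use the add-one convention, so the smallest attainable p is
#' 1/(n_permutations + 1).
#'
#' @param y Response association matrix.
#' @param xs A single predictor matrix or a (preferably named) list of them.
#' @param n_permutations Number of node permutations (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param exhaustive If `TRUE`, enumerate all n! node permutations instead
#'   of sampling (small n only); `n_permutations` is ignored.
#' @return An `"mrqap_dsp"` list: `coefficients` (intercept first),
#'   `t_values`, `r_squared`, `adj_r_squared`, `p_values` (per predictor),
#'   `n_permutations`, `n_dyads`, `n_nodes`, `statistic_kind`, `seed`.
#' @export
mrqap_dsp <- function(y, xs, n_permutations = 1000L, seed = NULL,
                      exhaustive = FALSE) {
  if (is.matrix(xs)) xs <- list(x = xs)
  stopifnot(length(xs) >= 1L)
  n <- nrow(y)
  if (n < 4L) stop("need at least 4 nodes", call. = FALSE)
  rost <- rownames(y)
  for (x in xs) {
    if (nrow(x) != n || (!is.null(rost) && !is.null(rownames(x)) &&
                         !identical(rownames(x), rost))) {
      stop("roster mismatch between response and predictor matrices",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  p <- length(xs)
  nd <- n * (n - 1L) / 2L
  yv <- .dyads(y)
  Xd <- vapply(xs, .dyads, numeric(nd))
  X <- cbind(`(Intercept)` = 1, Xd)
  if (qr(X)$rank < ncol(X)) {
    stop("singular design: collinear predictors among ",
         paste(names(xs), collapse = ", "), call. = FALSE)
  }
  obs <- .ols_t(X, yv)
  adj_r2 <- 1 - (1 - obs$r2) * (nd - 1) / (nd - p - 1)

  if (exhaustive) {
    perm_list <- .all_permutations(n)
    n_permutations <- length(perm_list)
  }
  exceed <- integer(p)
  for (i in seq_len(p)) {
    # residualize predictor i on the others (matrix-level, on dyads)
    others <- cbind(1, Xd[, -i, drop = FALSE])
    fit <- .ols_t(others, Xd[, i])
    resid_m <- .undyads(Xd[, i] - others %*% fit$coef, n)
    obs_t <- abs(obs$t[i + 1L])
    for (b in seq_len(n_permutations)) {
      pi_ <- if (exhaustive) perm_list[[b]] else sample.int(n)
      Xp <- X
      Xp[, i + 1L] <- .dyads(resid_m[pi_, pi_])
      pt <- .ols_t(Xp, yv)$t[i + 1L]
      if (abs(pt) >= obs_t - 1e-12) exceed[i] <- exceed[i] + 1L
    }
  }
  pvals <- (1 + exceed) / (1 + n_permutations)
  nm <- names(xs) %||% paste0("x", seq_len(p))
  structure(list(
    coefficients = stats::setNames(obs$coef, c("(Intercept)", nm)),
    t_values = stats::setNames(obs$t, c("(Intercept)", nm)),
    r_squared = obs$r2,
    adj_r_squared = adj_r2,
    p_values = stats::setNames(pvals, nm),
    n_permutations = as.integer(n_permutations),
    n_dyads = as.integer(nd),
    n_nodes = as.integer(n),
    statistic_kind = "t-statistic",
    seed = seed
  ), class = "mrqap_dsp")
}

#' @export
print.mrqap_dsp <- function(x, ...) {
  cat("MRQAP (double semi-partialling), ", x$n_permutations,
      " permutations, ", x$n_dyads, " dyads\n", sep = "")
  tab <- data.frame(coef = x$coefficients,
                    t = x$t_values,
                    p = c(NA, x$p_values))
  print(tab, digits = 4)
  cat("R2 =", format(x$r_squared, digits = 4),
      " adj. R2 =", format(x$adj_r_squared, digits = 4), "\n")
  invisible(x)
}

# all permutations of 1..n (used for exhaustive enumeration at small n)
.all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in .all_permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}
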