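# independent oracles and small fixture builders used across tests

# brute-force SRI tally: literal per-pair event counting
oracle_sri <- function(parties, a, b) {
  x <- ya <- yb <- 0L
  for (p in parties) {
    ina <- a %in% p
    inb <- b %in% p
    if (ina && inb) x <- x + 1L
    else if (ina) ya <- ya + 1L
    else if (inb) yb <- yb + 1L
  }
  if (x + ya + yb == 0L) 0 else x / (x + ya + yb)
}

# power-iteration eigenvector centrality, max-normalized
oracle_power_iteration <- function(m, iters = 10000, tol = 1e-14) {
  v <- rep(1, nrow(m))
  for (i in seq_len(iters)) {
    v2 <- as.vector(m %*% v)
    v2 <- v2 / sqrt(sum(v2^2))
    if (sqrt(sum((v2 - v)^2)) < tol) { v <- v2; break }
    v <- v2
  }
  v / max(v)
}

# naive double-loop modularity
oracle_modularity <- function(m, memb) {
  W2 <- sum(m)
  s <- unname(rowSums(m))
  q <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (memb[i] == memb[j]) q <- q + m[i, j] - s[i] * s[j] / W2
    }
  }
  q / W2
}

# all set partitions of n elements into at most kmax blocks, as label vectors
all_partitions <- function(n, kmax) {
  out <- list()
  rec <- function(labels, used) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (l in seq_len(min(used + 1L, kmax))) {
      rec(c(labels, l), max(used, l))
    }
  }
  rec(integer(0), 0L)
  out
}

# exhaustive modularity maximization over partitions into <= kmax blocks
oracle_best_modularity <- function(m, kmax = 4L) {
  best <- -Inf
  for (p in all_partitions(nrow(m), kmax)) {
    q <- oracle_modularity(m, p)
    if (q > best) best <- q
  }
  best
}

# exhaustive single-predictor MRQAP p-value over all node permutations,
# written against lm() rather than the package's fitting code
oracle_mrqap_p <- function(y, x) {
  dy <- y[lower.tri(y)]
  dx <- x[lower.tri(x)]
  n <- nrow(y)
  tstat <- function(xv) {
    f <- summary(stats::lm(dy ~ xv))
    unname(stats::coef(f)[2L, "t value"])
  }
  ex <- dx - mean(dx)                       # residual on intercept
  em <- matrix(0, n, n)
  em[lower.tri(em)] <- ex
  em <- em + t(em)
  obs <- abs(tstat(dx))
  perms <- list()
  gen <- function(v, rest) {
    if (!length(rest)) { perms[[length(perms) + 1L]] <<- v; return() }
    for (r in rest) gen(c(v, r), setdiff(rest, r))
  }
  gen(integer(0), seq_len(n))
  count <- 0L
  for (pi_ in perms) {
    ep <- em[pi_, pi_]
    if (abs(tstat(ep[lower.tri(ep)])) >= obs - 1e-12) count <- count + 1L
  }
  (1 + count) / (1 + length(perms))
}

# random weighted symmetric matrix with zero diagonal
random_network <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m <- m + t(m)
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}

# two-block planted weighted network on 8 nodes: strong within, weak between
planted_block_network <- function(seed, w_in = 1, w_out = 0.1) {
  set.seed(seed)
  n <- 8L
  block <- rep(1:2, each = 4L)
  m <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      base <- if (block[i] == block[j]) w_in else w_out
      m[i, j] <- m[j, i] <- base * stats::runif(1, 0.5, 1.5)
    }
  }
  dimnames(m) <- list(letters[1:n], letters[1:n])
  m
}

# videos data frame at one camera from start offsets in minutes
videos_at <- function(camera, offsets_min, prefix = camera) {
  origin <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  data.frame(
    video_id = paste0(prefix, "_v", seq_along(offsets_min)),
    camera_id = camera,
    start_timestamp = format(origin + offsets_min * 60,
                             "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    stringsAsFactors = FALSE
  )
}

# clip classification rows for one video
clip_rows <- function(video_id, verdicts_by_pos) {
  do.call(rbind, lapply(seq_along(verdicts_by_pos), function(p) {
    v <- verdicts_by_pos[[p]]
    if (!length(v)) return(NULL)
    data.frame(clip_id = paste0(video_id, "_c", p), video_id = video_id,
               position = p, annotator_id = paste0("a", seq_along(v)),
               verdict = v, stringsAsFactors = FALSE)
  }))
}
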