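test_that("strength sums edge weights", {
  m <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  m["a", "b"] <- m["b", "a"] <- 0.5
  m["a", "c"] <- m["c", "a"] <- 0.25
  expect_equal(node_strength(m, "a"), 0.75)
  expect_equal(node_strength(m, "b"), 0.5)
  expect_equal(unname(node_strength(m)["c"]), 0.25)
  expect_error(node_strength(m, "z"), "unknown node")
  # complete graph closed form: (n-1) w for every node
  n <- 6; w <- 0.3
  cm <- matrix(w, n, n); diag(cm) <- 0
  expect_equal(unname(node_strength(cm)), rep((n - 1) * w, n))
})

test_that("eigenvector centrality matches closed forms and power iteration", {
  # complete unweighted graph: all equal 1 by symmetry
  cm <- matrix(1, 5, 5); diag(cm) <- 0
  expect_equal(unname(eigenvector_centrality(cm)), rep(1, 5))
  # star with n leaves: leaf / center ratio = 1 / sqrt(n)
  n <- 9
  star <- matrix(0, n + 1, n + 1)
  star[1, 2:(n + 1)] <- star[2:(n + 1), 1] <- 1
  cen <- eigenvector_centrality(star)
  expect_equal(unname(cen[2:(n + 1)] / cen[1]), rep(1 / sqrt(n), n))
  # arbitrary weighted graphs agree with an independent power iteration
  for (seed in c(6, 60, 600)) {
    m <- random_network(6, seed)
    expect_equal(unname(eigenvector_centrality(m)),
                 oracle_power_iteration(m), tolerance = 1e-8)
  }
  expect_warning(z <- eigenvector_centrality(matrix(0, 3, 3)), "all-zero")
  expect_equal(unname(z), rep(0, 3))
})

test_that("modularity matches hand computations and a naive-summation oracle", {
  # one community scores exactly zero
  m <- random_network(6, 77)
  expect_equal(modularity_q(m, rep(1L, 6)), 0)
  # two disconnected equal cliques, split correctly: Q = 1/2
  cl <- matrix(0, 6, 6)
  cl[1:3, 1:3] <- 1; cl[4:6, 4:6] <- 1; diag(cl) <- 0
  expect_equal(modularity_q(cl, rep(1:2, each = 3)), 0.5)
  # random partitions against the double-loop oracle
  set.seed(14)
  for (i in 1:5) {
    memb <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_q(m, memb), oracle_modularity(m, memb),
                 tolerance = 1e-12)
  }
  expect_error(modularity_q(matrix(0, 3, 3), rep(1, 3)), "undefined")
})

test_that("leading-eigenvector splits recover obvious structure", {
  # two disconnected triangles -> the two components
  tri2 <- matrix(0, 6, 6)
  tri2[1:3, 1:3] <- 1; tri2[4:6, 4:6] <- 1; diag(tri2) <- 0
  dimnames(tri2) <- rep(list(letters[1:6]), 2)
  p <- leading_eigenvector_communities(tri2)
  expect_equal(p$n_communities, 2)
  expect_equal(length(unique(p$membership[1:3])), 1)
  expect_equal(length(unique(p$membership[4:6])), 1)
  expect_equal(p$modularity, 0.5)
  # complete uniform graph: no positive split
  cm <- matrix(0.4, 5, 5); diag(cm) <- 0
  expect_equal(leading_eigenvector_communities(cm)$n_communities, 1)
  # labels are contiguous from 0 and Q >= the trivial partition's 0
  dat <- random_network(8, 3)
  pr <- leading_eigenvector_communities(dat)
  expect_setequal(unique(pr$membership),
                  seq_len(pr$n_communities) - 1L)
  expect_gte(pr$modularity, 0)
})

test_that("planted two-block graphs attain brute-force-maximal modularity", {
  for (seed in c(1, 2, 3, 4, 5)) {
    m <- planted_block_network(seed)
    p <- leading_eigenvector_communities(m)
    expect_equal(p$modularity, oracle_best_modularity(m, kmax = 4L),
                 tolerance = 1e-10)
    expect_equal(p$n_communities, 2)
  }
})

test_that("membership agreement aligns labels optimally", {
  a <- stats::setNames(rep(1:4, each = 5), paste0("i", 1:20))
  expect_equal(membership_agreement(a, a)$pct_same, 100)
  # an arbitrary relabeling is still perfect agreement
  b <- stats::setNames(c(4:1)[a], names(a))
  expect_equal(membership_agreement(a, b)$pct_same, 100)
  # moving one individual of 20: 19/20 = 95%
  c_ <- a
  c_["i1"] <- 2
  r <- membership_agreement(a, c_)
  expect_equal(r$pct_same, 95)
  expect_equal(r$n_mismatched, 1)
  expect_error(membership_agreement(a, stats::setNames(1, "zz")),
               "share no individuals")
})

test_that("node relabeling permutes metrics and leaves summaries unchanged", {
  m <- random_network(7, 123)
  perm <- sample(7)
  mp <- m[perm, perm]
  expect_equal(node_strength(mp), node_strength(m)[perm])
  expect_equal(eigenvector_centrality(mp),
               eigenvector_centrality(m)[perm], tolerance = 1e-10)
  p1 <- leading_eigenvector_communities(m)
  p2 <- leading_eigenvector_communities(mp)
  expect_equal(p2$modularity, p1$modularity, tolerance = 1e-10)
  expect_equal(membership_agreement(p1, p2)$pct_same, 100)
})

test_that("partitions agree with an independent graph library on clean structure", {
  m <- planted_block_network(9, w_in = 1, w_out = 0.05)
  ours <- leading_eigenvector_communities(m)
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE)
  theirs <- igraph::cluster_leading_eigen(g)
  expect_equal(ours$n_communities, length(unique(igraph::membership(theirs))))
  expect_equal(
    membership_agreement(ours$membership,
                         stats::setNames(as.integer(igraph::membership(theirs)),
                                         rownames(m)))$pct_same, 100)
})

test_that("spearman correlation reproduces the rank-difference formula", {
  x <- 1:5
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with d^2 summing to 4
  expect_equal(spearman_rho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5)), 0.8)
  expect_warning(r <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
})
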