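test_that("global efficiency matches hand-computed examples", {
  expect_equal(global_efficiency(clique_matrix(1, 4)), 1)

  # 3-node unit path: pairs at distance 1, 1, 2 -> (1 + 1 + 0.5)/3
  P <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(global_efficiency(P), 5 / 6, tolerance = 1e-12)

  expect_equal(global_efficiency(matrix(0, 2, 2)), 0)
  expect_true(is.na(global_efficiency(matrix(0, 1, 1))))
})

test_that("global efficiency equals the brute-force oracle on random graphs", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    W <- matrix(runif(n * n) * (runif(n * n) < 0.6), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 0
    expect_equal(global_efficiency(W), oracle_global_efficiency(W),
                 tolerance = 1e-10)
  }
})

test_that("global efficiency is monotone in any single edge weight", {
  set.seed(21)
  W <- matrix(runif(36) * (runif(36) < 0.5), 6, 6)
  W <- (W + t(W)) / 2; diag(W) <- 0
  e0 <- global_efficiency(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)[5, ]
  W2 <- W
  W2[idx[1], idx[2]] <- W2[idx[2], idx[1]] <- W[idx[1], idx[2]] + 0.5
  expect_gte(global_efficiency(W2), e0)
})

test_that("local efficiency matches definitions and the subgraph oracle", {
  # neighbours of every clique node form a smaller unit clique
  expect_equal(local_efficiency(clique_matrix(1, 5)), rep(1, 5),
               ignore_attr = TRUE)

  # 4-node star: no neighbour-neighbour paths anywhere
  S <- matrix(0, 4, 4)
  S[1, 2:4] <- S[2:4, 1] <- 1
  expect_equal(local_efficiency(S), rep(0, 4), ignore_attr = TRUE)

  # random weighted graph vs exhaustive induced-subgraph oracle
  set.seed(33)
  W <- matrix(runif(64) * (runif(64) < 0.5), 8, 8)
  W <- (W + t(W)) / 2; diag(W) <- 0
  got <- local_efficiency(W)
  want <- vapply(1:8, function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(W[nb, nb, drop = FALSE])
  }, 0)
  expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("Louvain recovers planted structure and reference modularity values", {
  # single clique: one community, Q = 0
  lv1 <- louvain_partition(clique_matrix(1, 5), n_repeats = 4, seed = 1)
  expect_equal(lv1$n_communities, 1L)
  expect_equal(lv1$Q, 0, tolerance = 1e-12)

  # two disconnected equal cliques: Q = 2 * (1/2 - 1/4) = 0.5
  lv2 <- louvain_partition(clique_matrix(2, 4), n_repeats = 4, seed = 1)
  expect_equal(lv2$n_communities, 2L)
  expect_equal(lv2$Q, 0.5, tolerance = 1e-12)

  # noisy planted two-block matrix
  set.seed(8)
  B <- clique_matrix(2, 6) * 0.8 + matrix(runif(144, 0, 0.1), 12, 12)
  B <- (B + t(B)) / 2; diag(B) <- 0
  lv3 <- louvain_partition(B, n_repeats = 10, seed = 2)
  expect_equal(lv3$n_communities, 2L)
  planted <- rep(1:2, each = 6)
  expect_true(all(table(lv3$partition, planted) %in% c(0, 6)))

  # edgeless graph: single community, Q undefined
  lv4 <- louvain_partition(matrix(0, 3, 3), n_repeats = 2, seed = 1)
  expect_equal(lv4$n_communities, 1L)
  expect_true(is.na(lv4$Q))
})

test_that("returned Q is at least the one-community Q and grows with repeats", {
  set.seed(13)
  W <- matrix(runif(100) * (runif(100) < 0.3), 10, 10)
  W <- (W + t(W)) / 2; diag(W) <- 0
  lv <- louvain_partition(W, n_repeats = 8, seed = 3)
  expect_gte(lv$Q, 0)   # trivial partition has Q = 0 at gamma = 1
  q1 <- louvain_partition(W, n_repeats = 1, seed = 3)$Q
  expect_gte(lv$Q, q1)  # best-of-n is monotone in n for a fixed seed stream
})

test_that("metrics are invariant under simultaneous permutation", {
  set.seed(14)
  W <- matrix(runif(49) * (runif(49) < 0.5), 7, 7)
  W <- (W + t(W)) / 2; diag(W) <- 0
  perm <- sample(7)
  Wp <- W[perm, perm]
  expect_equal(global_efficiency(Wp), global_efficiency(W), tolerance = 1e-12)
  expect_equal(sort(local_efficiency(Wp)), sort(local_efficiency(W)),
               tolerance = 1e-12)
  expect_equal(louvain_partition(Wp, n_repeats = 5, seed = 9)$Q,
               louvain_partition(W, n_repeats = 5, seed = 9)$Q,
               tolerance = 1e-9)
})

test_that("network_metrics bundles all measures and writes a partition file", {
  nm <- network_metrics(clique_matrix(2, 4), n_repeats = 3, seed = 1)
  expect_equal(nm$n_communities, 2L)
  expect_equal(nm$Q, 0.5, tolerance = 1e-12)
  expect_equal(nm$global_efficiency,
               oracle_global_efficiency(clique_matrix(2, 4)), tolerance = 1e-10)
  path <- tempfile(fileext = ".tsv")
  write_partition(nm$partition, path)
  pf <- read.delim(path)
  expect_equal(nrow(pf), 8)
})
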