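test_that("closed-form graph metric identities hold", {
  n <- 6
  K <- matrix(1, n, n); diag(K) <- 0
  expect_equal(global_efficiency(K), 1.0)
  expect_equal(local_efficiency(K), rep(1.0, n))
  expect_equal(global_efficiency(matrix(0, n, n)), 0)
  expect_equal(mean_clustering(matrix(0, n, n)), 0)

  # 3-node unit-weight path: d13 = 2, E = (1+1+1/2)/3 per direction = 5/6
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  expect_equal(global_efficiency(P), 5 / 6)

  Tri <- matrix(1, 3, 3); diag(Tri) <- 0
  expect_equal(mean_clustering(Tri), 1.0)

  S <- matrix(0, 5, 5); S[1, 2:5] <- S[2:5, 1] <- 1  # star
  expect_equal(mean_clustering(S), 0)
  expect_equal(local_efficiency(S)[2], 0)  # leaf has one neighbour
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(10)
  for (r in 1:100) {
    n <- sample(4:10, 1)
    W <- rand_graph(n, density = runif(1, 0.3, 0.9))
    if (max(W) == 0) next
    expect_equal(global_efficiency(W), brute_global_eff(W), tolerance = 1e-10)
    expect_equal(mean_clustering(W), brute_clustering(W), tolerance = 1e-10)
    expect_equal(local_efficiency(W), brute_local_eff(W), tolerance = 1e-10)
  }
})

test_that("shortest path distances match igraph", {
  skip_if_not_installed("igraph")
  set.seed(11)
  for (r in 1:10) {
    W <- rand_graph(8, density = 0.5)
    if (max(W) == 0) next
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    Dig <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(netcog:::sp_dist(W), unname(Dig), tolerance = 1e-12)
  }
})

test_that("global efficiency is monotone under weight increases", {
  set.seed(12)
  W <- rand_graph(9, 0.4)
  e0 <- global_efficiency(W)
  W2 <- W
  off <- which(W == 0 & row(W) < col(W))
  pick <- sample(off, 1)
  W2[pick] <- 2; W2[cbind(col(W)[pick], row(W)[pick])] <- 2
  expect_gte(global_efficiency(W2), e0)
  W3 <- W * 1 # increase an existing weight
  on <- which(W > 0 & row(W) < col(W))[1]
  W3[on] <- W3[on] * 3; W3[cbind(col(W)[on], row(W)[on])] <- W3[on]
  expect_gte(global_efficiency(W3), e0)
})

test_that("clustering and local efficiency are scale invariant; global efficiency is not", {
  set.seed(13)
  W <- rand_graph(8, 0.6)
  expect_equal(mean_clustering(W * 7.3), mean_clustering(W))
  expect_equal(local_efficiency(W * 7.3), local_efficiency(W))
  expect_equal(global_efficiency(W * 2), 2 * global_efficiency(W))
})

test_that("indirect paths never reduce efficiency below the direct-edge bound", {
  set.seed(14)
  for (r in 1:10) {
    W <- rand_graph(8, 0.5)
    n <- nrow(W)
    direct <- sum(W) / (n * (n - 1))  # using only single-hop lengths 1/w
    expect_gte(global_efficiency(W) + 1e-12, direct)
  }
})

test_that("mean edge weight averages over mask edges, zeros included", {
  et <- all_edges(6L)
  m <- edge_mask(et$i[1:4], et$j[1:4], n_nodes = 6)
  W <- matrix(0, 6, 6)
  for (r in 1:4) W[et$i[r] + 1, et$j[r] + 1] <- W[et$j[r] + 1, et$i[r] + 1] <- 2.5
  expect_equal(mean_edge_weight(W, m), 2.5)
  # half the mask at 1, half at 0
  W2 <- matrix(0, 6, 6)
  for (r in 1:2) W2[et$i[r] + 1, et$j[r] + 1] <- W2[et$j[r] + 1, et$i[r] + 1] <- 1
  expect_equal(mean_edge_weight(W2, m), 0.5)
  set.seed(15)
  W3 <- rand_graph(6, 0.7)
  manual <- mean(sapply(1:4, function(r) W3[et$i[r] + 1, et$j[r] + 1]))
  expect_equal(mean_edge_weight(W3, m), manual)
  expect_error(mean_edge_weight(W3, edge_mask(integer(0), integer(0),
                                              n_nodes = 6)), "empty")
})

test_that("network_metrics returns aligned global and nodal tables", {
  cfg <- sim_config(seed = 30)
  cfg$cohorts$cohort_c$n <- 30
  co <- simulate_cohort(cfg, "cohort_c", weightings = "SC")
  m <- consistency_threshold(co$networks$SC, 0.25)
  res <- network_metrics(co$networks$SC, m, "SC")
  expect_equal(nrow(res$global), 30)
  expect_equal(dim(res$local), c(30, 85))
  expect_equal(res$global$participant_id, rownames(co$networks$SC))
  expect_true(all(res$global$global_efficiency >= 0))
  expect_true(all(res$global$mean_clustering >= 0 &
                  res$global$mean_clustering <= 1))
  # spot-check one participant against the standalone functions
  lin <- all_edges()$lin
  rows <- netcog:::mask_rows(m)
  W <- matrix(0, 85, 85)
  W[lin[rows]] <- co$networks$SC[7, rows]
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  expect_equal(res$global$global_efficiency[7], global_efficiency(W))
  expect_equal(res$local[7, ], local_efficiency(W),
               ignore_attr = TRUE)
})
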