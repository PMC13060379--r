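test_that("atlas satisfies its structural invariants", {
  a <- dk_atlas()
  expect_equal(nrow(a), 85)
  expect_equal(a$index, 0:84)
  expect_equal(sum(a$hemisphere == "midline"), 1)
  expect_equal(a$lobe[a$hemisphere == "midline"], "brainstem")
  expect_false(any(duplicated(a$name)))
  pairs <- table(a$pair_index)
  expect_equal(length(pairs), 42)
  expect_true(all(pairs == 2))
  for (pi in unique(na.omit(a$pair_index))) {
    pp <- a[!is.na(a$pair_index) & a$pair_index == pi, ]
    expect_setequal(pp$hemisphere, c("left", "right"))
    expect_equal(sub("^lh_", "", pp$name[1]), sub("^rh_", "", pp$name[2]))
  }
})

test_that("long-format and dense connectome files load as specified", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,i,j,weight", "p7,0,1,5", "p7,1,2,3",
               "p7,0,2,0"), tmp)
  cx <- read_connectome(tmp, "SC", n_nodes = 5)
  expect_equal(attr(cx, "participant_id"), "p7")
  expect_equal(cx[1, 2], 5)
  expect_equal(cx[2, 1], 5)
  expect_equal(cx[2, 3], 3)
  expect_equal(cx[1, 3], 0)
  expect_equal(sum(cx), 2 * (5 + 3))

  W <- matrix(0, 85, 85)
  W[4, 5] <- W[5, 4] <- 7
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_connectome(connectome(W), tmp2)
  c2 <- read_connectome(tmp2)
  expect_equal(sum(unclass(c2) > 0), 2)
  expect_equal(c2[4, 5], 7)
})

test_that("connectome writing then loading is an exact round trip", {
  set.seed(1)
  for (rep in 1:20) {
    W <- rand_graph(85, density = 0.3, maxw = 900)
    W <- W * exp(rnorm(1))       # arbitrary scale, full double precision
    cx <- connectome(W, "SC", "p1")
    tmp <- withr::local_tempfile(fileext = ".tsv")
    write_connectome(cx, tmp)
    c2 <- read_connectome(tmp, "SC")
    expect_identical(unclass(c2)[, ], unclass(cx)[, ])
  }
})

test_that("connectome validation rejects malformed matrices", {
  W <- matrix(0, 85, 85)
  W[1, 2] <- 1; W[2, 1] <- 1.1
  expect_error(connectome(W), "asymmetric")
  expect_error(connectome(matrix(0, 4, 5)), "square")
  W2 <- matrix(0, 85, 85); W2[1, 2] <- W2[2, 1] <- -1
  expect_error(connectome(W2), "negative")
  W3 <- matrix(0, 85, 85); W3[1, 2] <- W3[2, 1] <- 1.2
  expect_error(connectome(W3, "FA"), "FA")
  expect_silent(connectome(W3, "SC"))
})

test_that("apply_mask zeroes exactly the complement and is idempotent", {
  set.seed(2)
  W <- rand_graph(6, density = 1)
  cx <- connectome(W, "SC", "p")
  m4 <- edge_mask(c(0, 0, 1, 2), c(1, 2, 3, 5), n_nodes = 6)
  masked <- apply_mask(cx, m4)
  expect_equal(sum(masked[upper.tri(masked)] > 0), 4)
  for (r in seq_len(nrow(m4)))
    expect_equal(masked[m4$i[r] + 1, m4$j[r] + 1], W[m4$i[r] + 1, m4$j[r] + 1])
  expect_equal(unclass(apply_mask(masked, m4)), unclass(masked))

  full <- edge_mask(all_edges(6L)[, 1:2], n_nodes = 6)
  expect_equal(unclass(apply_mask(cx, full)), unclass(cx))
  none <- edge_mask(integer(0), integer(0), n_nodes = 6)
  expect_true(all(apply_mask(cx, none) == 0))
})

test_that("edge masks deduplicate, sort canonically and round-trip", {
  m <- edge_mask(c(3, 0, 3), c(1, 2, 1))
  expect_equal(m$i, c(0, 1))
  expect_equal(m$j, c(2, 3))
  expect_error(edge_mask(1, 1), "self-pairs")
  expect_error(edge_mask(0, 99), "atlas")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_edge_mask(m, tmp)
  m2 <- read_edge_mask(tmp)
  expect_equal(m2$i, m$i)
  expect_equal(m2$j, m$j)
})

test_that("streamline density divides by summed endpoint volumes", {
  W <- matrix(0, 85, 85)
  W[1, 2] <- W[2, 1] <- 100
  vol <- rep(50, 85)
  sd_net <- streamline_density(connectome(W), vol)
  expect_equal(sd_net[1, 2], 1.0)
  expect_equal(attr(sd_net, "weighting"), "SD")

  expect_true(all(streamline_density(connectome(matrix(0, 85, 85)),
                                     vol) == 0))
  set.seed(3)
  W2 <- rand_graph(85, 0.1, 500)
  v2 <- runif(85, 1000, 9000)
  sd2 <- streamline_density(connectome(W2), v2)
  for (k in 1:50) {
    i <- sample(85, 1); j <- sample(85, 1)
    if (i == j) next
    expect_equal(sd2[i, j], W2[i, j] / (v2[i] + v2[j]))
  }
  expect_error(streamline_density(connectome(W2), rep(0, 85)), "positive")
  expect_error(streamline_density(connectome(W2 / max(W2), "FA"), v2), "SC")
})

test_that("streamline density commutes with masking", {
  set.seed(4)
  W <- rand_graph(85, 0.2, 300)
  v <- runif(85, 1000, 9000)
  m <- consistency_threshold(rbind(as.numeric(W)[all_edges()$lin],
                                   as.numeric(W * 1.1)[all_edges()$lin],
                                   as.numeric(W * 0.9)[all_edges()$lin]),
                             density = 0.1)
  a <- streamline_density(apply_mask(connectome(W), m), v)
  b <- apply_mask(streamline_density(connectome(W), v), m)
  expect_equal(unclass(a), unclass(b))
})
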