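test_that("composite scores are standardized weighted sums", {
  set.seed(401)
  E <- matrix(rnorm(200 * 6), 200, 6)
  w <- c(1, 0, 0, 0, 0, 0)
  s <- composite_scores(E, w)
  expect_equal(s, as.numeric(scale(E[, 1])), ignore_attr = TRUE)

  expect_warning(z <- composite_scores(E, rep(0, 6)), "zero")
  expect_true(all(z == 0))

  # zero-variance column dropped with warning
  E2 <- E; E2[, 3] <- 5
  expect_warning(s2 <- composite_scores(E2, rep(0.2, 6)), "zero-variance")
  expect_equal(s2, composite_scores(E2[, -3], rep(0.2, 5)))

  # invariance to affine rescaling of a raw column
  E3 <- E; E3[, 2] <- 100 + 7 * E3[, 2]
  expect_equal(composite_scores(E3, rep(0.3, 6)),
               composite_scores(E, rep(0.3, 6)), tolerance = 1e-12)

  # train-moments mode reproduces manual standardisation
  ctr <- colMeans(E[1:100, ]); scl <- apply(E[1:100, ], 2, sd)
  s4 <- composite_scores(E[101:200, ], rep(0.5, 6), center = ctr, scale = scl)
  manual <- sweep(sweep(E[101:200, ], 2, ctr), 2, scl, "/") %*% rep(0.5, 6)
  expect_equal(s4, as.numeric(manual))
})

test_that("agreement correlations match direct computation", {
  expect_equal(beta_agreement(1:5, 1:5), 1.0)
  expect_equal(beta_agreement(1:5, -(1:5)), -1.0)
  a <- c(1, 2, 3, 4); b <- c(2, 4, 5, 9)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(beta_agreement(a, b), manual)
  expect_error(beta_agreement(1:4, 1:5), "length")
  expect_error(beta_agreement(rep(1, 4), 1:4), "zero-variance")
  expect_error(beta_agreement(c(1, 2, NA), c(1, NA, 3)), "3 usable")
})

test_that("hemispheric symmetry correlates bilateral homologues", {
  atlas <- dk_atlas()
  v <- rnorm(85)
  # perfectly mirrored: copy left values onto right homologues
  left <- atlas[atlas$hemisphere == "left", ]
  right <- atlas[atlas$hemisphere == "right", ]
  v2 <- v
  v2[right$index + 1] <- v[left$index[match(right$pair_index,
                                            left$pair_index)] + 1]
  expect_equal(hemispheric_symmetry(v2), 1.0)
  v3 <- v2
  v3[right$index + 1] <- -v3[right$index + 1]
  expect_equal(hemispheric_symmetry(v3), -1.0)
  # random vector against direct paired computation
  set.seed(402)
  v4 <- rnorm(85)
  lv <- v4[left$index + 1]
  rv <- v4[right$index[match(left$pair_index, right$pair_index)] + 1]
  expect_equal(hemispheric_symmetry(v4), cor(lv, rv))
})

test_that("edge classification counts form a partition with correct percentages", {
  atlas <- dk_atlas()
  li <- atlas$index[atlas$hemisphere == "left"]
  m_left <- edge_mask(rep(li[1], 5), li[2:6])
  cl <- classify_edges(m_left)
  h <- cl$hemisphere_table
  expect_equal(h$pct[h$category == "intra_hemispheric"], 100.0)
  expect_equal(h$count[h$category == "inter"], 0)

  set.seed(403)
  et <- all_edges()
  rows <- sample(3570, 400)
  m <- edge_mask(et$i[rows], et$j[rows])
  cl2 <- classify_edges(m)
  h2 <- cl2$hemisphere_table
  base <- h2[h2$category %in% c("intra_left", "intra_right", "inter",
                                "brainstem_involved"), ]
  expect_equal(sum(base$count), nrow(m))
  expect_equal(sum(cl2$lobe_table$count), nrow(m))
  expect_equal(nrow(cl2$edges), nrow(m))
  expect_lt(abs(sum(base$pct) - 100), 0.21)  # rounding slack
  # lobe-pair matrix totals: diagonal once, off-diagonal twice
  lp <- cl2$lobe_pair_counts
  expect_equal((sum(lp) + sum(diag(lp))) / 2, nrow(m))
})

test_that("toy atlas classification matches hand counts", {
  toy <- data.frame(index = 0:5,
                    name = c("l1", "l2", "r1", "r2", "mid", "l3"),
                    hemisphere = c("left", "left", "right", "right",
                                   "midline", "left"),
                    lobe = c("frontal", "parietal", "frontal", "parietal",
                             "brainstem", "frontal"),
                    pair_index = c(0, 1, 0, 1, NA, 2))
  m <- edge_mask(c(0, 0, 1, 2, 0), c(1, 2, 3, 3, 4), n_nodes = 6)
  cl <- classify_edges(m, atlas = toy)
  h <- cl$hemisphere_table
  expect_equal(h$count[h$category == "intra_left"], 1)   # (0,1)
  expect_equal(h$count[h$category == "intra_right"], 1)  # (2,3)
  expect_equal(h$count[h$category == "inter"], 2)        # (0,2), (1,3)
  expect_equal(h$count[h$category == "brainstem_involved"], 1)  # (0,4)
  l <- cl$lobe_table
  expect_equal(l$count[l$category == "intra_lobe"], 2)   # (0,2), (2,3)? no:
  # (0,2) frontal-frontal and (1,3) parietal-parietal are intra-lobe;
  # (0,1), (2,3) cross lobes; (0,4) frontal-brainstem is inter.
  expect_equal(l$count[l$category == "inter_lobe"], 3)
})

test_that("external map correlation matches by region name", {
  atlas <- dk_atlas()
  v <- rnorm(85)
  cortical <- atlas[!(atlas$lobe %in% c("subcortical", "brainstem")), ]
  emap <- data.frame(region = cortical$name,
                     value = v[cortical$index + 1])
  r <- map_correlation(v, emap)
  expect_equal(as.numeric(r), 1.0)
  expect_equal(attr(r, "n_matched"), 68)

  emap2 <- emap
  emap2$region[1] <- "not_a_region"
  r2 <- map_correlation(v, emap2)
  expect_equal(attr(r2, "n_matched"), 67)
  expect_equal(attr(r2, "unmatched"), "not_a_region")

  # permutation null is centred on zero
  set.seed(404)
  rs <- replicate(300, {
    em <- emap; em$value <- sample(em$value)
    as.numeric(map_correlation(v, em))
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(300))

  # constructed covariance reproduces the direct computation
  set.seed(405)
  em3 <- emap
  em3$value <- 0.5 * v[cortical$index + 1] + rnorm(68)
  expect_equal(as.numeric(map_correlation(v, em3)),
               cor(v[cortical$index + 1], em3$value))
})
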