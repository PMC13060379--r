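# direct construction of association test data: a metric whose correlation
# with latent g is known, plus a battery measuring g
make_assoc_data <- function(n, beta, lambda = seq(0.3, 0.7, length.out = 5),
                            moderation = 0) {
  g <- rnorm(n)
  age <- runif(n, 40, 80)
  az <- as.numeric(scale(age))
  b <- beta + moderation * az
  x <- b * g + sqrt(max(1 - beta^2, 0)) * rnorm(n)
  d <- make_battery_from_g(g, lambda)
  list(metric = x, tests = d, g = g,
       covars = data.frame(age = age,
                           sex = sample(c("F", "M"), n, replace = TRUE)))
}

make_battery_from_g <- function(g, lambda) {
  n <- length(g)
  p <- length(lambda)
  outer(g, lambda) + matrix(rnorm(n * p), n, p) %*% diag(sqrt(1 - lambda^2))
}

test_that("both estimators recover an injected standardized effect of 0.2", {
  # recovery is judged on the mean over replicate cohorts at n = 2000 so
  # the check reflects the estimator, not a single cohort's sampling noise
  fs_betas <- numeric(3)
  sem <- NULL
  for (s in 1:3) {
    cfg <- sim_config(seed = 200 + s)
    cfg$effects$beta_global["SC"] <- 0.2
    cfg$cohorts$cohort_a$n <- 2000
    co <- simulate_cohort(cfg, "cohort_a", weightings = "SC")
    x <- rowMeans(co$networks$SC)
    fs <- netg_assoc(x, co$tests, co$covars, estimator = "fs")
    fs_betas[s] <- fs$beta
    if (s == 1) {
      sem <- netg_assoc(x, co$tests, co$covars, estimator = "sem")
      # the two-stage fallback tracks the one-step SEM closely
      expect_lt(abs(fs$beta - sem$beta), 0.02)
      expect_equal(sem$ci_lo, sem$beta - 1.96 * sem$se)
      expect_equal(sem$ci_hi, sem$beta + 1.96 * sem$se)
    }
  }
  expect_lt(abs(mean(fs_betas) - 0.2), 0.05)
})

test_that("a metric equal to true g gives a coefficient near one", {
  set.seed(202)
  g <- rnorm(1500)
  y <- make_battery_from_g(g, c(0.9, 0.85, 0.8))
  cv <- data.frame(age = runif(1500, 40, 80),
                   sex = sample(c("F", "M"), 1500, TRUE))
  a <- netg_assoc(g, y, cv, estimator = "fs")
  expect_gt(a$beta, 0.9)
  expect_lt(a$beta, 1.1)
})

test_that("coefficients are invariant to affine rescaling of the metric", {
  set.seed(203)
  d <- make_assoc_data(800, 0.25)
  a1 <- netg_assoc(d$metric, d$tests, d$covars, estimator = "fs")
  a2 <- netg_assoc(5 + 3 * d$metric, d$tests, d$covars, estimator = "fs")
  expect_equal(a1$beta, a2$beta, tolerance = 1e-10)
  expect_equal(a1$se, a2$se, tolerance = 1e-10)
})

test_that("standard errors shrink roughly as 1/sqrt(n)", {
  set.seed(204)
  d <- make_assoc_data(8000, 0.2)
  a_small <- netg_assoc(d$metric[1:2000], d$tests[1:2000, ],
                        d$covars[1:2000, ], estimator = "fs")
  a_large <- netg_assoc(d$metric, d$tests, d$covars, estimator = "fs")
  ratio <- a_small$se / a_large$se
  expect_gt(ratio, 2 * 0.8)
  expect_lt(ratio, 2 * 1.2)
})

test_that("age moderation is recovered and narrow-age cohorts are skipped", {
  set.seed(205)
  d <- make_assoc_data(20000, 0.2, moderation = 0.05)
  m <- netg_moderation(d$metric, d$tests, d$covars, estimator = "fs")
  expect_lt(abs(m$beta - 0.05), 0.02)

  d2 <- make_assoc_data(300, 0.2)
  d2$covars$age <- runif(300, 71, 74)
  expect_warning(sk <- netg_moderation(d2$metric, d2$tests, d2$covars),
                 "skipped")
  expect_equal(sk$flag, "skipped_narrow_age")
  expect_true(is.na(sk$beta))
})

test_that("a null metric is not associated (coefficients centred on zero)", {
  set.seed(206)
  betas <- replicate(30, {
    d <- make_assoc_data(400, 0)
    netg_assoc(rnorm(400), d$tests, d$covars, estimator = "fs")$beta
  })
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(30))
})

test_that("batch association preserves order and flags degenerate columns", {
  set.seed(207)
  d <- make_assoc_data(300, 0.2)
  M <- cbind(m1 = d$metric, m2 = rnorm(300), m3 = rep(1, 300),
             m4 = rnorm(300))
  res <- netg_assoc_batch(M, d$tests, d$covars, estimator = "fs")
  expect_equal(res$metric_id, c("m1", "m2", "m3", "m4"))
  expect_equal(res$flag[3], "zero-variance metric")
  expect_true(is.na(res$beta[3]))
  expect_false(anyNA(res$beta[-3]))
  # the vectorised path agrees with per-column fits
  one <- netg_assoc(M[, 1], d$tests, d$covars, estimator = "fs")
  expect_equal(res$beta[1], one$beta, tolerance = 1e-8)
  expect_equal(res$se[1], one$se, tolerance = 1e-8)
})

test_that("association validates inputs", {
  set.seed(208)
  d <- make_assoc_data(100, 0.2)
  expect_error(netg_assoc(rep(1, 100), d$tests, d$covars), "zero-variance")
  expect_error(netg_assoc(d$metric[1:30], d$tests[1:30, ], d$covars[1:30, ]),
               "usable participants")
})
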