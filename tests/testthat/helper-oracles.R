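# Independent brute-force oracles used to verify the package's graph
# metrics, REML pooling and factor-model fits. These deliberately use
# different algorithms from the implementation (Floyd-Warshall instead of
# Dijkstra, exhaustive triple/pair enumeration, grid search instead of
# Fisher scoring, Wishart discrepancy instead of casewise FIML).

# all-pairs shortest paths by Floyd-Warshall on lengths 1/w
fw_dist <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && W[i, j] > 0) D[i, j] <- 1 / W[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

brute_global_eff <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- fw_dist(W)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

brute_clustering <- function(W) {
  n <- nrow(W)
  Wn <- W / max(W)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      acc <- acc + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
    }
    ci[i] <- acc / (k * (k - 1))
  }
  mean(ci)
}

brute_local_eff <- function(W) {
  n <- nrow(W)
  Wn <- W / max(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(Wn[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    D <- fw_dist(Wn[nb, nb, drop = FALSE])
    acc <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b || !is.finite(D[a, b]) || D[a, b] <= 0) next
      acc <- acc + (Wn[i, nb[a]] * Wn[i, nb[b]] / D[a, b])^(1 / 3)
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# random symmetric nonnegative weight matrix
rand_graph <- function(n, density = 0.5, maxw = 5) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  on <- up[runif(length(up)) < density]
  W[on] <- runif(length(on), 0.1, maxw)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

# restricted (REML) log-likelihood of the random-effects model, maximised
# over a fine tau^2 grid
grid_reml <- function(betas, ses, tau2_max = 1, steps = 40001) {
  v <- ses^2
  restll <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * betas) / sum(w)
    -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (betas - mu)^2))
  }
  grid <- seq(0, tau2_max, length.out = steps)
  ll <- vapply(grid, restll, 0)
  t2 <- grid[which.max(ll)]
  # refine around the grid optimum
  lo <- max(0, t2 - 2 * (grid[2] - grid[1]))
  hi <- t2 + 2 * (grid[2] - grid[1])
  grid2 <- seq(lo, hi, length.out = 20001)
  ll2 <- vapply(grid2, restll, 0)
  t2 <- grid2[which.max(ll2)]
  w <- 1 / (v + t2)
  list(tau2 = t2, beta = sum(w * betas) / sum(w), se = 1 / sqrt(sum(w)))
}

# complete-data ML of the one-factor model from sample moments, by
# minimising the Wishart discrepancy F = log|Sigma| + tr(S Sigma^-1)
wishart_ml_loadings <- function(y) {
  n <- nrow(y); p <- ncol(y)
  S <- cov(y) * (n - 1) / n
  obj <- function(par) {
    lam <- par[1:p]
    th <- exp(par[p + 1:p])
    Sig <- tcrossprod(lam) + diag(th, p)
    ld <- determinant(Sig, logarithm = TRUE)$modulus
    as.numeric(ld + sum(diag(solve(Sig, S))))
  }
  e <- eigen(S, symmetric = TRUE)
  lam0 <- e$vectors[, 1] * sqrt(e$values[1])
  if (sum(lam0) < 0) lam0 <- -lam0
  par0 <- c(lam0, log(pmax(diag(S) - lam0^2, 0.05)))
  opt <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  lam <- opt$par[1:p]
  if (lam[1] < 0) lam <- -lam
  lam
}

# small one-factor battery with optional MCAR missingness
make_battery <- function(n, lambda, miss = 0, rescov_pairs = NULL,
                         rescov_val = 0) {
  g <- rnorm(n)
  p <- length(lambda)
  theta <- 1 - lambda^2
  eps <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(theta))
  if (!is.null(rescov_pairs)) {
    for (pr in rescov_pairs) {
      sh <- rnorm(n, 0, sqrt(rescov_val))
      for (k in pr) {
        eps[, k] <- sqrt((theta[k] - rescov_val) / theta[k]) * eps[, k] + sh
      }
    }
  }
  y <- outer(g, lambda) + eps
  if (miss > 0) y[matrix(runif(n * p) < miss, n, p)] <- NA
  list(y = y, g = g)
}
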