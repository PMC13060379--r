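# One-factor confirmatory factor model of general cognitive function (g)
# with full-information maximum likelihood (FIML) for missing test scores.
#
# Model: x_j = nu_j + lambda_j * g + eps_j, g ~ N(0, 1),
# eps ~ N(0, Theta) with Theta diagonal apart from user-specified residual
# covariances. Identification fixes the latent variance to 1 (all loadings
# free) with a first-loading-positive sign convention. The casewise FIML
# log-likelihood sums, over each participant's observed-variable pattern,
# -0.5 * (k log 2pi + log|Sigma_o| + (x_o - mu_o)' Sigma_o^{-1} (x_o - mu_o)).

# assemble Theta from diagonal variances and residual-covariance values
build_theta <- function(thd, rescov, rcv) {
  Theta <- diag(thd, length(thd))
  if (length(rcv))
    for (k in seq_along(rcv)) {
      a <- rescov[k, 1]; b <- rescov[k, 2]
      Theta[a, b] <- Theta[b, a] <- rcv[k]
    }
  Theta
}

# pairwise-complete covariance, nudged to positive definiteness
robust_start_cov <- function(y) {
  S <- suppressWarnings(stats::cov(y, use = "pairwise.complete.obs"))
  S[is.na(S)] <- 0
  e <- eigen(S, symmetric = TRUE)
  lo <- max(e$values) * 1e-6
  e$vectors %*% diag(pmax(e$values, lo), nrow(S)) %*% t(e$vectors)
}

#' Fit a one-factor g model by FIML
#'
#' Confirmatory factor analysis of a battery of cognitive test scores with
#' a single latent factor (g), estimated by full-information maximum
#' likelihood so participants with missing scores contribute through their
#' observed-variable pattern. The latent variance is fixed to 1 and all
#' loadings are free; the first loading is constrained positive in sign.
#'
#' @param tests numeric matrix or data.frame (participants x tests) with
#'   `NA` for missing scores. At least 3 tests are required for
#'   identification and each test must be observed for at least 2
#'   participants.
#' @param rescov optional residual covariances: a list of length-2 vectors
#'   or a two-column matrix of test indices (1-based) or test names.
#' @param se compute standard errors of the free parameters from the
#'   observed information (numerical Hessian at the optimum)?
#' @param max_iter,reltol optimiser budget (BFGS on the free parameters;
#'   residual variances are log-parameterised).
#' @return An object of class `gcfa` with elements `loadings` (raw),
#'   `std_loadings`, `theta` (residual covariance matrix), `nu`
#'   (intercepts), `loglik`, `loglik_sat`, `loglik_base`, `df`, `fit`
#'   (CFI, TLI, RMSEA, SRMR), `converged`, `n_used`, and the inputs needed
#'   for factor scoring. Rows with no observed tests are dropped from the
#'   likelihood and reported in `n_dropped`.
#' @seealso [predict.gcfa()] for factor scores, [fit_indices()] for the fit
#'   statistics.
#' @export
gcfa <- function(tests, rescov = NULL, se = TRUE, max_iter = 500,
                 reltol = 1e-10) {
  y <- as.matrix(tests)
  storage.mode(y) <- "double"
  p <- ncol(y)
  if (p < 3) stop("at least 3 tests are required for identification")
  if (is.null(colnames(y))) colnames(y) <- paste0("test", seq_len(p))
  if (any(colSums(!is.na(y)) < 2))
    stop("each test must be observed for at least 2 participants")
  keep <- rowSums(!is.na(y)) > 0
  n_dropped <- sum(!keep)
  y <- y[keep, , drop = FALSE]
  n <- nrow(y)

  rescov <- normalize_rescov(rescov, colnames(y))
  r <- nrow(rescov)

  # starting values from pairwise moments: first eigenvector of the
  # covariance scaled to a one-factor decomposition
  S0 <- robust_start_cov(y)
  e <- eigen(S0, symmetric = TRUE)
  lam0 <- e$vectors[, 1] * sqrt(max(e$values[1], 1e-8))
  if (sum(lam0) < 0) lam0 <- -lam0
  thd0 <- pmax(diag(S0) - lam0^2, 0.1 * pmax(diag(S0), 1e-6))
  nu0 <- colMeans(y, na.rm = TRUE)
  par0 <- c(nu0, lam0, log(thd0), rep(0, r))

  unpack <- function(par) {
    nu <- par[1:p]
    lambda <- par[p + 1:p]
    thd <- exp(par[2 * p + 1:p])
    rcv <- if (r) par[3 * p + 1:r] else numeric(0)
    list(nu = nu, lambda = lambda, Theta = build_theta(thd, rescov, rcv))
  }
  zero_eta <- numeric(n)
  nll <- function(par) {
    q <- unpack(par)
    v <- fiml_nll(y, zero_eta, q$nu, q$lambda, q$Theta, 1.0)
    if (!is.finite(v)) v <- 1e12
    v
  }
  opt <- optim(par0, nll, method = "BFGS",
               control = list(maxit = max_iter, reltol = reltol))
  q <- unpack(opt$par)
  flip <- q$lambda[1] < 0
  if (flip) q$lambda <- -q$lambda
  loglik <- -opt$value

  sat <- fiml_saturated(y)
  llb <- fiml_baseline_loglik(y)
  npar_m <- 3 * p + r
  df_m <- p * (p + 1) / 2 - (2 * p + r)
  df_b <- p * (p + 1) / 2 - p
  srmr <- srmr_listwise(y, q$lambda, q$Theta)
  fit <- fit_indices(loglik, sat$loglik, llb, df_m, df_b, n, srmr = srmr)

  vc <- se_tab <- NULL
  if (se) {
    H <- optim(opt$par, nll, method = "BFGS",
               control = list(maxit = 0), hessian = TRUE)$hessian
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc)) {
      sev <- suppressWarnings(sqrt(pmax(diag(vc), 0)))
      se_tab <- list(nu = sev[1:p], lambda = sev[p + 1:p])
    }
  }

  std <- q$lambda / sqrt(q$lambda^2 + diag(q$Theta))
  structure(list(
    loadings = setNames(q$lambda, colnames(y)),
    std_loadings = setNames(std, colnames(y)),
    theta = q$Theta, nu = setNames(q$nu, colnames(y)),
    rescov = rescov, loglik = loglik, loglik_sat = sat$loglik,
    loglik_base = llb, df = c(model = df_m, baseline = df_b),
    npar = npar_m, fit = fit,
    converged = opt$convergence == 0, opt_counts = opt$counts,
    n_used = n, n_dropped = n_dropped, se = se_tab, vcov = vc,
    test_names = colnames(y)), class = "gcfa")
}

normalize_rescov <- function(rescov, nms) {
  if (is.null(rescov) || (is.list(rescov) && !length(rescov)))
    return(matrix(integer(0), 0, 2))
  if (is.list(rescov)) rescov <- do.call(rbind, rescov)
  rescov <- as.matrix(rescov)
  if (!nrow(rescov)) return(matrix(integer(0), 0, 2))
  if (ncol(rescov) != 2) stop("rescov must be pairs of test indices/names")
  if (is.character(rescov)) {
    m <- matrix(match(rescov, nms), ncol = 2)
    if (anyNA(m)) stop("unknown test name in rescov")
    rescov <- m
  }
  rescov <- t(apply(rescov, 1, sort))
  if (any(rescov < 1) || any(rescov > length(nms)))
    stop("rescov index outside the battery")
  if (any(rescov[, 1] == rescov[, 2])) stop("rescov pairs must be distinct tests")
  if (anyDuplicated(paste(rescov[, 1], rescov[, 2])))
    stop("duplicated rescov pair")
  storage.mode(rescov) <- "integer"
  rescov
}

#' Saturated-model FIML estimates by EM
#'
#' Maximum-likelihood mean vector and unrestricted covariance matrix of a
#' multivariate normal with data missing at random, by the standard EM
#' algorithm on sufficient statistics. Used as the saturated reference for
#' fit indices under missingness.
#'
#' @param y numeric matrix with `NA` missing values; every row must have at
#'   least one observed entry.
#' @param max_iter,tol EM budget (absolute log-likelihood change).
#' @return list with `mu`, `Sigma`, `loglik`, `iterations`.
#' @export
fiml_saturated <- function(y, max_iter = 500, tol = 1e-7) {
  y <- as.matrix(y)
  n <- nrow(y); p <- ncol(y)
  mu <- colMeans(y, na.rm = TRUE)
  Sigma <- robust_start_cov(y) * (n - 1) / n
  obs <- !is.na(y)
  pat <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  groups <- split(seq_len(n), pat)
  zero_eta <- numeric(n)
  ll_of <- function(mu, Sigma)
    -fiml_nll(y, zero_eta, mu, numeric(p), Sigma, 1.0)
  ll <- ll_of(mu, Sigma)
  for (it in seq_len(max_iter)) {
    sx <- numeric(p)
    sxx <- matrix(0, p, p)
    for (g in groups) {
      o <- which(obs[g[1], ])
      m <- setdiff(seq_len(p), o)
      Y <- y[g, , drop = FALSE]
      if (length(m)) {
        So <- Sigma[o, o, drop = FALSE]
        B <- solve(So, Sigma[o, m, drop = FALSE])     # |o| x |m|
        resid <- sweep(Y[, o, drop = FALSE], 2, mu[o])
        Y[, m] <- matrix(mu[m], nrow(Y), length(m), byrow = TRUE) +
          resid %*% B
        Cmm <- Sigma[m, m, drop = FALSE] -
          t(Sigma[o, m, drop = FALSE]) %*% B
        add <- matrix(0, p, p)
        add[m, m] <- Cmm * nrow(Y)
        sxx <- sxx + add
      }
      sx <- sx + colSums(Y)
      sxx <- sxx + crossprod(Y)
    }
    mu_new <- sx / n
    Sigma_new <- sxx / n - tcrossprod(mu_new)
    Sigma_new <- (Sigma_new + t(Sigma_new)) / 2
    ll_new <- ll_of(mu_new, Sigma_new)
    mu <- mu_new; Sigma <- Sigma_new
    if (is.finite(ll_new) && abs(ll_new - ll) < tol) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  list(mu = mu, Sigma = Sigma, loglik = ll, iterations = it)
}

# independence (baseline) model: per-variable Gaussian ML on observed cells
fiml_baseline_loglik <- function(y) {
  sum(vapply(seq_len(ncol(y)), function(j) {
    x <- y[, j]; x <- x[!is.na(x)]
    m <- mean(x); v <- mean((x - m)^2)
    sum(dnorm(x, m, sqrt(v), log = TRUE))
  }, 0))
}

# SRMR on the correlation metric from listwise-complete sample moments
srmr_listwise <- function(y, lambda, Theta) {
  cc <- y[complete.cases(y), , drop = FALSE]
  if (nrow(cc) < ncol(y) + 2) return(NA_real_)
  Rs <- cor(cc)
  Si <- tcrossprod(lambda) + Theta
  Ri <- stats::cov2cor(Si)
  lt <- lower.tri(Rs)
  sqrt(mean((Rs[lt] - Ri[lt])^2))
}

#' Structural-equation fit indices from log-likelihoods
#'
#' Computes CFI, TLI and RMSEA from the model, saturated and baseline
#' (independence) log-likelihoods via the likelihood-ratio statistics
#' `T = 2 (ll_sat - ll)`. SRMR is a residual-based index and is passed
#' through from the caller (see [gcfa()], which computes it on the
#' correlation metric from listwise-complete moments).
#'
#' @param loglik_model,loglik_saturated,loglik_baseline log-likelihoods of
#'   the fitted, saturated, and independence models on the same data.
#' @param df_model,df_baseline model degrees of freedom.
#' @param n sample size.
#' @param srmr optional standardised root mean squared residual to carry
#'   into the result.
#' @return named numeric vector `(CFI, TLI, RMSEA, SRMR)`.
#' @export
fit_indices <- function(loglik_model, loglik_saturated, loglik_baseline,
                        df_model, df_baseline, n, srmr = NA_real_) {
  if (df_baseline <= 0) stop("baseline degrees of freedom must be positive")
  Tm <- 2 * (loglik_saturated - loglik_model)
  Tb <- 2 * (loglik_saturated - loglik_baseline)
  cfi <- 1 - max(Tm - df_model, 0) / max(Tb - df_baseline, Tm - df_model, 0)
  tli <- ((Tb / df_baseline) - (Tm / df_model)) / ((Tb / df_baseline) - 1)
  rmsea <- sqrt(max(Tm - df_model, 0) / (df_model * n))
  c(CFI = cfi, TLI = tli, RMSEA = rmsea, SRMR = srmr)
}

#' Factor scores from a fitted g model
#'
#' Regression-method scores using each participant's observed-variable
#' pattern: `g_hat = lambda' Sigma_o^{-1} (x_o - mu_o)`, standardised to
#' mean 0 and SD 1 over the scored sample. Participants with no observed
#' tests receive `NA`.
#'
#' @param object a fitted [gcfa()] model.
#' @param newdata matrix/data.frame of test scores (defaults must be
#'   supplied; columns matched to the fitted battery by name when named).
#' @param standardize standardise the scores over the sample (default TRUE).
#' @param ... unused.
#' @return numeric vector of g scores, one per row of `newdata`.
#' @export
predict.gcfa <- function(object, newdata, standardize = TRUE, ...) {
  y <- as.matrix(newdata)
  if (!is.null(colnames(y)) && all(object$test_names %in% colnames(y)))
    y <- y[, object$test_names, drop = FALSE]
  p <- length(object$loadings)
  if (ncol(y) != p) stop("newdata must have one column per fitted test")
  lambda <- unname(object$loadings)
  Sigma <- tcrossprod(lambda) + object$theta
  nu <- unname(object$nu)
  n <- nrow(y)
  scores <- rep(NA_real_, n)
  obs <- !is.na(y)
  pat <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  for (g in split(seq_len(n), pat)) {
    o <- which(obs[g[1], ])
    if (!length(o)) next
    w <- solve(Sigma[o, o, drop = FALSE], lambda[o])
    resid <- sweep(y[g, o, drop = FALSE], 2, nu[o])
    scores[g] <- as.numeric(resid %*% w)
  }
  if (sum(is.na(scores)))
    message(sum(is.na(scores)), " participant(s) with no observed tests: NA score")
  if (standardize) {
    mu <- mean(scores, na.rm = TRUE); s <- sd(scores, na.rm = TRUE)
    scores <- (scores - mu) / s
  }
  scores
}

#' @export
logLik.gcfa <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n_used,
            class = "logLik")
}

#' @export
coef.gcfa <- function(object, standardized = TRUE, ...) {
  if (standardized) object$std_loadings else object$loadings
}

#' @method print gcfa
#' @export
print.gcfa <- function(x, ...) {
  cat("One-factor g model (FIML), n =", x$n_used)
  if (x$n_dropped) cat(" (", x$n_dropped, "all-missing rows dropped)")
  cat("\nConverged:", x$converged, " logLik:", format(x$loglik), "\n")
  cat("Standardized loadings:\n")
  print(round(x$std_loadings, 3))
  cat(sprintf("Fit: CFI %.3f  TLI %.3f  RMSEA %.3f  SRMR %.3f\n",
              x$fit["CFI"], x$fit["TLI"], x$fit["RMSEA"], x$fit["SRMR"]))
  invisible(x)
}

#' @method summary gcfa
#' @export
summary.gcfa <- function(object, ...) {
  tab <- data.frame(loading = object$loadings,
                    std_loading = object$std_loadings,
                    resid_var = diag(object$theta))
  if (!is.null(object$se)) {
    tab$se <- object$se$lambda
    tab$z <- tab$loading / tab$se
  }
  out <- list(table = tab, fit = object$fit, df = object$df,
              loglik = object$loglik, n = object$n_used,
              converged = object$converged)
  class(out) <- "summary.gcfa"
  out
}

#' @method print summary.gcfa
#' @export
print.summary.gcfa <- function(x, ...) {
  cat("One-factor g model (FIML), n =", x$n, "\n\n")
  print(round(x$table, 4))
  cat(sprintf("\nlogLik %.2f  df(model) %d  df(baseline) %d\n", x$loglik,
              x$df["model"], x$df["baseline"]))
  cat(sprintf("Fit: CFI %.3f  TLI %.3f  RMSEA %.3f  SRMR %.3f\n",
              x$fit["CFI"], x$fit["TLI"], x$fit["RMSEA"], x$fit["SRMR"]))
  invisible(x)
}

#' @export
plot.gcfa <- function(x, ...) {
  graphics::barplot(x$std_loadings, las = 2, ylim = c(0, 1),
                    ylab = "standardized loading on g",
                    main = "g measurement model", ...)
  invisible(x)
}
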