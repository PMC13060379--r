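# Cohort-level structural regression of latent g on a network metric,
# adjusting for age, sex and site.
#
# Primary estimator: a one-step MIMIC model fitted by FIML —
#   tests:  x_j = nu_j + lambda_j * g + eps_j          (measurement part)
#   latent: g   = gamma' C + zeta,  zeta ~ N(0, psi)   (structural part)
# with C the covariate block (standardised metric, standardised age, sex,
# site dummies, optionally the age x metric interaction). Identification by
# marker loading (lambda_1 = 1, psi free); coefficients are reported fully
# standardised, dividing by the model-implied SD of g.
#
# Fallback estimator ("fs"): regression-method factor scores regressed on
# the same covariates by OLS, with a reliability disattenuation (the score
# variance lambda_o' Sigma_oo^{-1} lambda_o per missingness pattern) so the
# coefficient targets the same standardised quantity.

# covariate design matrix; metric and age standardised within cohort
build_design <- function(metric, covars, moderation = FALSE) {
  n <- length(metric)
  if (var(metric) == 0) stop("zero-variance metric")
  mz <- as.numeric(scale(metric))
  cols <- list(metric = mz)
  if (!is.null(covars$age)) {
    if (sd(covars$age) == 0) stop("zero-variance age")
    cols$age <- as.numeric(scale(covars$age))
  }
  if (!is.null(covars$sex)) {
    s <- covars$sex
    if (!is.numeric(s)) s <- as.integer(factor(s)) - 1L
    if (length(unique(s)) > 1) cols$sex <- as.numeric(s)
  }
  if (!is.null(covars$site)) {
    f <- factor(covars$site)
    if (nlevels(f) > 1) {
      D <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(D) <- paste0("site", levels(f)[-1])
      for (k in seq_len(ncol(D))) cols[[colnames(D)[k]]] <- D[, k]
    }
  }
  if (moderation) cols$age_x_metric <- cols$metric * cols$age
  X <- do.call(cbind, cols)
  sv <- svd(scale(X, scale = FALSE), nu = 0, nv = 0)$d
  kappa <- sv[1] / max(sv[length(sv)], .Machine$double.eps)
  if (kappa > 1e8) stop(sprintf("collinear covariates (condition number %.3g)", kappa))
  X
}

# one-step MIMIC fit by FIML; start values from a measurement-model fit
fit_mimic <- function(y, X, rescov, gstart = NULL, max_iter = 500,
                      reltol = 1e-10) {
  p <- ncol(y); q <- ncol(X); r <- nrow(rescov)
  if (is.null(gstart)) gstart <- gcfa(y, rescov = rescov, se = FALSE)
  lam1 <- gstart$loadings[1]
  if (abs(lam1) < 1e-6) lam1 <- 1
  lam0 <- unname(gstart$loadings / lam1)
  # gamma start from disattenuated factor-score OLS, mapped to marker scale
  fs <- fs_scores(gstart, y)
  g0 <- fs$scores
  gamma0 <- tryCatch(qr.coef(qr(cbind(1, X)), g0 / mean(fs$rho2))[-1] * lam1,
                     error = function(e) rep(0, q))
  gamma0[!is.finite(gamma0)] <- 0
  psi0 <- max(lam1^2 * 0.8, 1e-3)
  nu0 <- unname(gstart$nu)
  thd0 <- pmax(diag(gstart$theta), 1e-6)
  rcv0 <- if (r) gstart$theta[rescov] else numeric(0)
  par0 <- c(nu0, lam0[-1], log(thd0), rcv0, gamma0, log(psi0))

  unpack <- function(par) {
    nu <- par[1:p]
    lambda <- c(1, par[p + seq_len(p - 1)])
    thd <- exp(par[(2 * p - 1) + 1:p])
    rcv <- if (r) par[(3 * p - 1) + seq_len(r)] else numeric(0)
    gamma <- par[(3 * p - 1 + r) + 1:q]
    psi <- exp(par[3 * p + r + q])
    list(nu = nu, lambda = lambda, Theta = build_theta(thd, rescov, rcv),
         gamma = gamma, psi = psi)
  }
  nll <- function(par) {
    s <- unpack(par)
    eta <- as.numeric(X %*% s$gamma)
    v <- fiml_nll(y, eta, s$nu, s$lambda, s$Theta, s$psi)
    if (!is.finite(v)) v <- 1e12
    v
  }
  opt <- optim(par0, nll, method = "BFGS",
               control = list(maxit = max_iter, reltol = reltol))
  H <- optim(opt$par, nll, method = "BFGS", control = list(maxit = 0),
             hessian = TRUE)$hessian
  vc <- tryCatch(solve(H), error = function(e) NULL)
  s <- unpack(opt$par)
  list(par = opt$par, unpack = unpack, est = s, vcov = vc,
       loglik = -opt$value, converged = opt$convergence == 0, nll = nll)
}

# standardised coefficient of one covariate term plus delta-method SE
standardize_term <- function(fit, X, term) {
  Sx <- stats::cov(X)
  q <- ncol(X)
  bfun <- function(par) {
    s <- fit$unpack(par)
    sdg <- sqrt(as.numeric(t(s$gamma) %*% Sx %*% s$gamma) + s$psi)
    unname(s$gamma[term] / sdg)
  }
  beta <- bfun(fit$par)
  se <- NA_real_
  if (!is.null(fit$vcov)) {
    np <- length(fit$par)
    gr <- numeric(np)
    h <- pmax(abs(fit$par) * 1e-5, 1e-7)
    for (k in (np - q):np) {       # beta depends only on gamma and psi
      up <- dn <- fit$par
      up[k] <- up[k] + h[k]; dn[k] <- dn[k] - h[k]
      gr[k] <- (bfun(up) - bfun(dn)) / (2 * h[k])
    }
    v <- as.numeric(t(gr) %*% fit$vcov %*% gr)
    if (is.finite(v) && v > 0) se <- sqrt(v)
  }
  c(beta = beta, se = se)
}

# factor scores in raw (unstandardised) form plus per-row reliability
fs_scores <- function(gfit, y) {
  y <- as.matrix(y)
  lambda <- unname(gfit$loadings)
  Sigma <- tcrossprod(lambda) + gfit$theta
  nu <- unname(gfit$nu)
  n <- nrow(y)
  scores <- rep(NA_real_, n)
  rho2 <- rep(NA_real_, n)
  obs <- !is.na(y)
  pat <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  for (g in split(seq_len(n), pat)) {
    o <- which(obs[g[1], ])
    if (!length(o)) next
    w <- solve(Sigma[o, o, drop = FALSE], lambda[o])
    scores[g] <- as.numeric(sweep(y[g, o, drop = FALSE], 2, nu[o]) %*% w)
    rho2[g] <- sum(w * lambda[o])
  }
  list(scores = scores, rho2 = rho2)
}

assoc_row <- function(cohort_id, weighting, scale, metric_id, beta, se, n,
                      flag = "") {
  data.frame(cohort_id = cohort_id, weighting = weighting, scale = scale,
             metric_id = metric_id, beta = beta, se = se,
             ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
             p = 2 * pnorm(-abs(beta / se)), n = n, flag = flag,
             stringsAsFactors = FALSE)
}

#' Association between a network metric and latent g
#'
#' Fits the structural regression of g (measured by the cohort's test
#' battery) on a per-participant network metric, adjusting for age, sex and
#' site, and returns the metric's fully standardised coefficient with a
#' Wald confidence interval and two-sided normal p-value.
#'
#' @param metric numeric vector, one value per participant.
#' @param tests matrix/data.frame of cognitive test scores (NA = missing).
#' @param covars data.frame with columns `age`, `sex` and optionally
#'   `site` (dropped if single-level), aligned with `metric`.
#' @param rescov residual covariances for the measurement model
#'   (see [gcfa()]).
#' @param estimator `"sem"` for the one-step FIML MIMIC model (default) or
#'   `"fs"` for the disattenuated factor-score regression.
#' @param gfit optional pre-fitted [gcfa()] measurement model used for
#'   starting values (`"sem"`) or scoring (`"fs"`).
#' @param moderation if `TRUE`, an age x metric interaction (both
#'   standardised, so per SD of age) is added and reported instead of the
#'   metric main effect.
#' @param cohort_id,weighting,scale,metric_id labels copied to the output.
#' @param min_n minimum participants with complete metric/covariates.
#' @return one-row data.frame: `cohort_id, weighting, scale, metric_id,
#'   beta, se, ci_lo, ci_hi, p, n, flag`.
#' @export
netg_assoc <- function(metric, tests, covars, rescov = NULL,
                       estimator = c("sem", "fs"), gfit = NULL,
                       moderation = FALSE, cohort_id = "cohort",
                       weighting = "SC", scale = "global",
                       metric_id = "metric", min_n = 50) {
  estimator <- match.arg(estimator)
  y <- as.matrix(tests)
  ok <- is.finite(metric) & rowSums(!is.na(y)) > 0
  for (v in intersect(c("age", "sex", "site"), names(covars)))
    ok <- ok & !is.na(covars[[v]])
  if (sum(ok) < min_n)
    stop(sprintf("only %d usable participants (min_n = %d)", sum(ok), min_n))
  y <- y[ok, , drop = FALSE]
  metric <- metric[ok]
  covars <- covars[ok, , drop = FALSE]
  rescov <- normalize_rescov(rescov, colnames(y))
  X <- build_design(metric, covars, moderation = moderation)
  term <- if (moderation) which(colnames(X) == "age_x_metric") else 1L
  n <- nrow(y)

  if (estimator == "sem") {
    fit <- fit_mimic(y, X, rescov, gstart = gfit)
    st <- standardize_term(fit, X, term)
    flag <- if (fit$converged) "" else "nonconvergence"
    return(assoc_row(cohort_id, weighting, scale, metric_id,
                     unname(st["beta"]), unname(st["se"]), n, flag))
  }
  if (is.null(gfit)) gfit <- gcfa(y, rescov = rescov, se = FALSE)
  fs <- fs_scores(gfit, y)
  rel <- mean(fs$rho2, na.rm = TRUE)
  fm <- lm(fs$scores ~ X)
  cf <- summary(fm)$coefficients
  row <- 1 + term
  assoc_row(cohort_id, weighting, scale, metric_id,
            cf[row, 1] / rel, cf[row, 2] / rel, n,
            flag = if (gfit$converged) "" else "nonconvergence")
}

#' Age moderation of a network-g association
#'
#' Adds a standardised age x metric interaction to the structural model and
#' reports its coefficient (change in the network-g association per SD
#' increase in age). Cohorts whose age SD falls below `age_sd_floor`
#' (narrow-age designs, where the moderator is essentially constant) are
#' skipped with a warning and a flagged row rather than an error.
#'
#' @inheritParams netg_assoc
#' @param age_sd_floor minimum age SD in years for the analysis to run.
#' @return one-row data.frame as [netg_assoc()]; when skipped, `beta` and
#'   `se` are `NA` and `flag` is `"skipped_narrow_age"`.
#' @export
netg_moderation <- function(metric, tests, covars, rescov = NULL,
                            estimator = "sem", gfit = NULL,
                            cohort_id = "cohort", weighting = "SC",
                            scale = "global", metric_id = "metric",
                            age_sd_floor = 3) {
  if (sd(covars$age, na.rm = TRUE) < age_sd_floor) {
    warning(sprintf("age SD %.2f below floor %.2f: moderation skipped",
                    sd(covars$age, na.rm = TRUE), age_sd_floor))
    return(assoc_row(cohort_id, weighting, scale, metric_id, NA_real_,
                     NA_real_, sum(is.finite(metric)),
                     flag = "skipped_narrow_age"))
  }
  netg_assoc(metric, tests, covars, rescov = rescov, estimator = estimator,
             gfit = gfit, moderation = TRUE, cohort_id = cohort_id,
             weighting = weighting, scale = scale, metric_id = metric_id)
}

#' Batch associations over many metrics
#'
#' Maps [netg_assoc()] over the columns of a metric table (e.g. 85 nodal
#' local efficiencies, or the masked edge weights) in deterministic column
#' order. Per-metric failures (zero variance, non-convergence) become
#' flagged rows; the batch never aborts. For the `"fs"` estimator the
#' regressions are vectorised across columns, which is the practical choice
#' at edge scale; the measurement model is fitted once and shared.
#'
#' @param metrics numeric matrix (participants x metrics) with column names
#'   as metric ids.
#' @inheritParams netg_assoc
#' @param progress print a note every `progress` columns (0 = silent).
#' @return data.frame with one row per metric column.
#' @export
netg_assoc_batch <- function(metrics, tests, covars, rescov = NULL,
                             estimator = c("sem", "fs"), gfit = NULL,
                             moderation = FALSE, cohort_id = "cohort",
                             weighting = "SC", scale = "node",
                             progress = 0) {
  estimator <- match.arg(estimator)
  metrics <- as.matrix(metrics)
  ids <- colnames(metrics)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(metrics)))
  y <- as.matrix(tests)
  rescov <- normalize_rescov(rescov, colnames(y))
  if (is.null(gfit)) gfit <- gcfa(y, rescov = rescov, se = FALSE)

  if (estimator == "fs" && !moderation) {
    return(fs_batch(metrics, ids, y, covars, gfit, cohort_id, weighting,
                    scale))
  }
  out <- vector("list", ncol(metrics))
  for (k in seq_len(ncol(metrics))) {
    out[[k]] <- tryCatch(
      netg_assoc(metrics[, k], y, covars, rescov = rescov,
                 estimator = estimator, gfit = gfit,
                 moderation = moderation, cohort_id = cohort_id,
                 weighting = weighting, scale = scale, metric_id = ids[k]),
      error = function(e)
        assoc_row(cohort_id, weighting, scale, ids[k], NA_real_, NA_real_,
                  nrow(y), flag = conditionMessage(e)))
    if (progress > 0 && k %% progress == 0)
      message("associations: ", k, "/", ncol(metrics))
  }
  do.call(rbind, out)
}

# vectorised factor-score regression across metric columns via
# Frisch-Waugh: residualise scores and each standardised metric on the
# shared covariates, then slope + classical SE per column
fs_batch <- function(metrics, ids, y, covars, gfit, cohort_id, weighting,
                     scale) {
  ok <- rowSums(!is.na(y)) > 0
  for (v in intersect(c("age", "sex", "site"), names(covars)))
    ok <- ok & !is.na(covars[[v]])
  y <- y[ok, , drop = FALSE]
  metrics <- metrics[ok, , drop = FALSE]
  covars <- covars[ok, , drop = FALSE]
  n <- nrow(y)
  fs <- fs_scores(gfit, y)
  rel <- mean(fs$rho2, na.rm = TRUE)
  C <- build_design(seq_len(n), covars)[, -1, drop = FALSE]  # covariates only
  C1 <- cbind(1, C)
  qrC <- qr(C1)
  rg <- qr.resid(qrC, fs$scores)
  sds <- apply(metrics, 2, sd)
  bad <- !is.finite(sds) | sds == 0
  Z <- scale(metrics[, !bad, drop = FALSE])
  RZ <- qr.resid(qrC, Z)
  ss <- colSums(RZ^2)
  bhat <- colSums(RZ * rg) / ss
  dfree <- n - ncol(C1) - 1
  rss <- colSums((rg - sweep(RZ, 2, bhat, "*"))^2)
  sehat <- sqrt(rss / dfree / ss)
  res <- assoc_row(cohort_id, weighting, scale, ids[!bad], bhat / rel,
                   sehat / rel, n)
  if (any(bad)) {
    res <- rbind(res, assoc_row(cohort_id, weighting, scale, ids[bad],
                                NA_real_, NA_real_, n,
                                flag = "zero-variance metric"))
    res <- res[match(ids, res$metric_id), ]
    rownames(res) <- NULL
  }
  res
}
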