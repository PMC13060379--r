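# Random-effects meta-analysis of cohort-level standardised coefficients,
# with REML estimation of the between-study variance tau^2 (via metafor,
# the standard tool for this step), and Benjamini-Hochberg FDR control
# across metric families.

#' Random-effects pooling of cohort effects
#'
#' Pools k study coefficients under the random-effects model
#' `beta_i ~ N(mu, v_i + tau^2)` with tau^2 estimated by restricted maximum
#' likelihood. Inverse-variance weights `w_i = 1/(v_i + tau^2)` give the
#' meta-analytic coefficient, its SE `1/sqrt(sum w_i)`, Wald confidence
#' interval and two-sided p-value. If REML fails to converge the
#' DerSimonian-Laird moment estimator is used instead and flagged — with
#' only three cohorts REML can be fragile, so the fallback is explicit
#' rather than silent.
#'
#' @param betas numeric vector of study coefficients (k >= 2).
#' @param ses positive standard errors, same length.
#' @param metric_id label copied to the output.
#' @return one-row data.frame: `metric_id, beta_meta, se_meta, ci_lo,
#'   ci_hi, p, tau2, k, estimator`.
#' @export
meta_pool <- function(betas, ses, metric_id = "metric") {
  if (length(betas) < 2) stop("need at least two studies")
  if (length(ses) != length(betas)) stop("betas and ses differ in length")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("ses must be positive")
  fit <- tryCatch(
    suppressWarnings(
      metafor::rma(yi = betas, sei = ses, method = "REML", test = "z",
                   control = list(maxiter = 100, threshold = 1e-10))),
    error = function(e) NULL)
  estimator <- "REML"
  if (is.null(fit)) {
    fit <- metafor::rma(yi = betas, sei = ses, method = "DL", test = "z")
    estimator <- "DL"
  }
  data.frame(metric_id = metric_id, beta_meta = as.numeric(fit$beta),
             se_meta = fit$se, ci_lo = fit$ci.lb, ci_hi = fit$ci.ub,
             p = fit$pval, tau2 = fit$tau2, k = length(betas),
             estimator = estimator, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up BH adjustment: q-values are the cumulative-minimum adjusted
#' p-values, and hypotheses with `q_value <= q` are rejected.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @param q FDR level (default 0.05).
#' @return list with `q_values` and logical `reject`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  qv <- p.adjust(pvalues, method = "BH")
  list(q_values = qv, reject = !is.na(qv) & qv <= q)
}

#' Three-way meta-analysis over metric families
#'
#' Pools per-cohort association tables metric by metric and applies BH-FDR
#' within each family, one family per weighting x scale combination (e.g.
#' the 85 SC nodes form one family, the FA edges another). Metric ids must
#' align across cohorts; rows flagged unusable in any cohort are pooled
#' over the remaining cohorts when at least two are available, otherwise
#' flagged.
#'
#' @param tables list of per-cohort data.frames as returned by
#'   [netg_assoc_batch()] (columns `weighting, scale, metric_id, beta, se`).
#' @param q FDR level.
#' @return data.frame with one row per metric: pooling results plus
#'   `q_value` and `significant`.
#' @export
meta_batch <- function(tables, q = 0.05) {
  stopifnot(length(tables) >= 2)
  ref <- tables[[1]][, c("weighting", "scale", "metric_id")]
  for (t in tables[-1]) {
    if (nrow(t) != nrow(ref) || !all(t$metric_id == ref$metric_id))
      stop("metric ids are misaligned across cohorts")
  }
  out <- vector("list", nrow(ref))
  for (r in seq_len(nrow(ref))) {
    b <- vapply(tables, function(t) t$beta[r], 0)
    s <- vapply(tables, function(t) t$se[r], 0)
    usable <- is.finite(b) & is.finite(s) & s > 0
    if (sum(usable) < 2) {
      out[[r]] <- data.frame(metric_id = ref$metric_id[r],
                             beta_meta = NA_real_, se_meta = NA_real_,
                             ci_lo = NA_real_, ci_hi = NA_real_,
                             p = NA_real_, tau2 = NA_real_,
                             k = sum(usable), estimator = "unpooled",
                             stringsAsFactors = FALSE)
    } else {
      out[[r]] <- meta_pool(b[usable], s[usable],
                            metric_id = ref$metric_id[r])
    }
  }
  res <- cbind(ref[, c("weighting", "scale")], do.call(rbind, out))
  res$q_value <- NA_real_
  res$significant <- FALSE
  for (fam in split(seq_len(nrow(res)),
                    paste(res$weighting, res$scale, sep = ":"))) {
    adj <- bh_fdr(res$p[fam], q = q)
    res$q_value[fam] <- adj$q_values
    res$significant[fam] <- adj$reject
  }
  rownames(res) <- NULL
  res
}
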