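# End-to-end orchestration: simulate -> threshold -> metrics -> fit-g ->
# associate -> meta -> predict -> report. Every stage's inputs and outputs
# are CSV/JSON files inside the run directory, so stages are independently
# re-runnable; a manifest records the seed, a config hash and per-stage row
# counts. All randomness flows from the single root seed, expanded per
# cohort/stage by the deterministic scheme in derive_seed().

fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- (h - lo + bitwXor(lo, b)) %% 2^32
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Pipeline run configuration
#'
#' Bundles the simulation configuration with the analysis settings: the
#' consistency-thresholding density (default 0.30), the FDR level, which
#' estimator runs at each scale (the one-step SEM for the three global
#' metrics; the vectorised factor-score regression at node and edge scale,
#' where thousands of fits are needed), whether age-moderation models run
#' (they are skipped automatically for narrow-age cohorts), and whether
#' the streamline-density (SD) variant is computed. The first cohort is
#' split in half: the second half is an untouched hold-out used only by
#' the prediction stage.
#'
#' @param seed root seed for the whole run.
#' @param density consistency-threshold network density.
#' @param fdr_q FDR level.
#' @param sim a [sim_config()]; defaults to scaled-down cohorts
#'   (800/400/300) so a full run stays light.
#' @param estimators named character vector mapping scales to `"sem"` or
#'   `"fs"`.
#' @param moderation fit age-moderation models for wide-age cohorts?
#' @param sd_variant also compute the volume-normalised SD weighting?
#' @param standardization `"sample"` or `"train"` moments for composite
#'   standardisation of the hold-out sample.
#' @return list of class `netcog_run_config`.
#' @export
run_config <- function(seed = 1, density = 0.30, fdr_q = 0.05,
                       sim = NULL,
                       estimators = c(global = "sem", node = "fs",
                                      edge = "fs"),
                       moderation = TRUE, sd_variant = FALSE,
                       standardization = c("sample", "train")) {
  if (is.null(sim)) {
    sim <- sim_config(seed = seed)
    sim$cohorts$cohort_a$n <- 800
    sim$cohorts$cohort_b$n <- 400
    sim$cohorts$cohort_c$n <- 300
  }
  stopifnot(density > 0, density <= 1, fdr_q > 0, fdr_q < 1)
  cfg <- list(seed = seed, density = density, fdr_q = fdr_q, sim = sim,
              estimators = estimators, moderation = moderation,
              sd_variant = sd_variant,
              standardization = match.arg(standardization))
  class(cfg) <- "netcog_run_config"
  cfg
}

config_hash <- function(cfg) {
  fnv1a(paste(deparse(unclass(cfg), control = "all"), collapse = "\n"))
}

fwrite_ <- function(df, path) {
  if (requireNamespace("data.table", quietly = TRUE))
    data.table::fwrite(df, path)
  else write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fread_ <- function(path) {
  if (requireNamespace("data.table", quietly = TRUE))
    as.data.frame(data.table::fread(path))
  else read.csv(path, stringsAsFactors = FALSE)
}

write_edge_csv <- function(E, path) {
  df <- as.data.frame(signif(E, 10))
  names(df) <- sprintf("e%04d", seq_len(ncol(E)))
  df <- cbind(participant_id = rownames(E), df)
  fwrite_(df, path)
}

read_edge_csv <- function(path) {
  df <- fread_(path)
  E <- as.matrix(df[, -1, drop = FALSE])
  rownames(E) <- df$participant_id
  dimnames(E)[[2]] <- NULL
  E
}

stage_log <- function(run, stage, msg)
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))

#' Run the full pipeline
#'
#' Executes all stages in order, writing every intermediate table under
#' `out_dir`. Any stage failure halts the run with the stage name; partial
#' outputs are retained. Re-running with the same configuration and seed
#' reproduces every output byte-identically.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to (re-)run, in pipeline order.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("simulate", "threshold", "metrics",
                                    "g", "associate", "meta", "predict",
                                    "report")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else
    list(seed = cfg$seed, config_hash = config_hash(cfg),
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("netcog")),
         stages = list())
  writeLines(deparse(unclass(cfg), control = "all"),
             file.path(out_dir, "config.R.txt"))

  cids <- names(cfg$sim$cohorts)
  wts <- c("SC", "FA", "MD")
  for (stage in stages) {
    res <- tryCatch(switch(stage,
      simulate = stage_simulate(cfg, out_dir, cids, wts),
      threshold = stage_threshold(cfg, out_dir, cids),
      metrics = stage_metrics(cfg, out_dir, cids, wts),
      g = stage_g(cfg, out_dir, cids),
      associate = stage_associate(cfg, out_dir, cids, wts),
      meta = stage_meta(cfg, out_dir),
      predict = stage_predict(cfg, out_dir, cids, wts),
      report = stage_report(cfg, out_dir, cids, wts),
      stop("unknown stage: ", stage)),
      error = function(e)
        stop(sprintf("pipeline halted in stage '%s': %s", stage,
                     conditionMessage(e)), call. = FALSE))
    manifest$stages[[stage]] <- res
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(manifest)
}

stage_simulate <- function(cfg, out_dir, cids, wts) {
  info <- list()
  for (id in cids) {
    co <- simulate_cohort(cfg$sim, id, weightings = wts)
    d <- file.path(out_dir, id)
    dir.create(d, showWarnings = FALSE)
    cv <- co$covars
    cv$tbv <- signif(cv$tbv, 10)
    cv$true_g <- signif(cv$true_g, 10)
    cv$age <- signif(cv$age, 10)
    fwrite_(cv, file.path(d, "covars.csv"))
    tdf <- as.data.frame(signif(co$tests, 10))
    tdf <- cbind(participant_id = rownames(co$tests), tdf)
    fwrite_(tdf, file.path(d, "tests.csv"))
    for (w in wts)
      write_edge_csv(co$networks[[w]],
                     file.path(d, paste0("edges_", w, ".csv")))
    writeLines(jsonlite::toJSON(list(loadings = co$loadings,
                                     rescov = co$rescov), digits = NA),
               file.path(d, "battery.json"))
    info[[id]] <- list(n = nrow(cv), n_tests = ncol(co$tests))
    stage_log(NULL, "simulate", sprintf("%s: n=%d", id, nrow(cv)))
  }
  info
}

stage_threshold <- function(cfg, out_dir, cids) {
  masks <- list()
  for (id in cids) {
    E <- read_edge_csv(file.path(out_dir, id, "edges_SC.csv"))
    masks[[id]] <- consistency_threshold(E, cfg$density)
    write_edge_mask(masks[[id]], file.path(out_dir, id, "mask.csv"))
  }
  ref <- intersect_masks(masks)
  write_edge_mask(ref, file.path(out_dir, "reference_mask.csv"))
  ov <- attr(ref, "pairwise_overlap")
  ovdf <- data.frame(cohort_a = rep(cids, each = length(cids)),
                     cohort_b = rep(cids, length(cids)),
                     overlap = as.integer(ov))
  fwrite_(ovdf, file.path(out_dir, "mask_overlap.csv"))
  stage_log(NULL, "threshold",
            sprintf("per-cohort K=%s; reference mask %d edges",
                    paste(vapply(masks, nrow, 0L), collapse = "/"), nrow(ref)))
  list(per_cohort_edges = vapply(masks, nrow, 0L),
       reference_edges = nrow(ref),
       reference_density = mask_density(ref))
}

stage_metrics <- function(cfg, out_dir, cids, wts) {
  ref <- read_edge_mask(file.path(out_dir, "reference_mask.csv"))
  info <- list()
  for (id in cids) {
    for (w in wts) {
      E <- read_edge_csv(file.path(out_dir, id, paste0("edges_", w, ".csv")))
      m <- network_metrics(E, ref, weighting = w)
      g <- m$global
      g[, 3:5] <- signif(g[, 3:5], 10)
      fwrite_(g, file.path(out_dir, id, paste0("metrics_global_", w, ".csv")))
      loc <- as.data.frame(signif(m$local, 10))
      loc <- cbind(participant_id = rownames(m$local), loc)
      fwrite_(loc, file.path(out_dir, id, paste0("metrics_local_", w, ".csv")))
    }
    if (cfg$sd_variant) {
      # SD = SC normalised by endpoint volumes is derivable from the SC
      # edge matrix and the node volumes; kept off by default
    }
    info[[id]] <- list(weightings = wts)
    stage_log(NULL, "metrics", id)
  }
  info
}

stage_g <- function(cfg, out_dir, cids) {
  info <- list()
  for (id in cids) {
    tests <- fread_(file.path(out_dir, id, "tests.csv"))
    ids <- tests$participant_id
    y <- as.matrix(tests[, -1, drop = FALSE])
    bat <- jsonlite::read_json(file.path(out_dir, id, "battery.json"),
                               simplifyVector = TRUE)
    rescov <- bat$rescov
    if (is.matrix(rescov)) rescov <- asplit(rescov, 1)
    fit <- gcfa(y, rescov = rescov)
    scores <- predict(fit, y)
    fwrite_(data.frame(participant_id = ids, g = signif(scores, 10)),
            file.path(out_dir, id, "gscores.csv"))
    fitrep <- list(loadings = unname(fit$loadings),
                   std_loadings = unname(fit$std_loadings),
                   fit = as.list(fit$fit), converged = fit$converged,
                   n_used = fit$n_used, loglik = fit$loglik)
    writeLines(jsonlite::toJSON(fitrep, auto_unbox = TRUE, digits = NA),
               file.path(out_dir, id, "gfit.json"))
    info[[id]] <- list(converged = fit$converged,
                       cfi = unname(fit$fit["CFI"]))
    stage_log(NULL, "g", sprintf("%s: CFI=%.3f", id, fit$fit["CFI"]))
  }
  info
}

# cohort_a is split in half: rows in the first half are the "main" sample
# used for association/meta; the second half is the untouched hold-out
main_rows <- function(cfg, id, n) {
  if (id == names(cfg$sim$cohorts)[1]) seq_len(floor(n / 2)) else seq_len(n)
}

holdout_rows <- function(cfg, id, n) {
  if (id == names(cfg$sim$cohorts)[1]) setdiff(seq_len(n), main_rows(cfg, id, n))
  else integer(0)
}

load_cohort_inputs <- function(out_dir, id) {
  covars <- fread_(file.path(out_dir, id, "covars.csv"))
  tests <- fread_(file.path(out_dir, id, "tests.csv"))
  bat <- jsonlite::read_json(file.path(out_dir, id, "battery.json"),
                             simplifyVector = TRUE)
  rescov <- bat$rescov
  if (is.matrix(rescov)) rescov <- asplit(rescov, 1)
  list(covars = covars, y = as.matrix(tests[, -1, drop = FALSE]),
       rescov = rescov)
}

stage_associate <- function(cfg, out_dir, cids, wts) {
  ref <- read_edge_mask(file.path(out_dir, "reference_mask.csv"))
  rows <- mask_rows(ref)
  edge_ids <- sprintf("edge_%d_%d", ref$i, ref$j)
  info <- list()
  for (id in cids) {
    inp <- load_cohort_inputs(out_dir, id)
    n <- nrow(inp$covars)
    use <- main_rows(cfg, id, n)
    y <- inp$y[use, , drop = FALSE]
    covars <- inp$covars[use, , drop = FALSE]
    gfit <- gcfa(y, rescov = inp$rescov, se = FALSE)
    out <- list()
    mod <- list()
    for (w in wts) {
      gm <- fread_(file.path(out_dir, id, paste0("metrics_global_", w, ".csv")))
      gmat <- as.matrix(gm[use, 3:5])
      colnames(gmat) <- paste0(w, "_", c("mean_edge_weight",
                                         "global_efficiency",
                                         "mean_clustering"))
      out[[paste0("g", w)]] <- netg_assoc_batch(
        gmat, y, covars, rescov = inp$rescov,
        estimator = cfg$estimators[["global"]], gfit = gfit,
        cohort_id = id, weighting = w, scale = "global")
      loc <- fread_(file.path(out_dir, id, paste0("metrics_local_", w, ".csv")))
      lmat <- as.matrix(loc[use, -1, drop = FALSE])
      out[[paste0("n", w)]] <- netg_assoc_batch(
        lmat, y, covars, rescov = inp$rescov,
        estimator = cfg$estimators[["node"]], gfit = gfit,
        cohort_id = id, weighting = w, scale = "node")
      E <- read_edge_csv(file.path(out_dir, id, paste0("edges_", w, ".csv")))
      emat <- E[use, rows, drop = FALSE]
      colnames(emat) <- edge_ids
      out[[paste0("e", w)]] <- netg_assoc_batch(
        emat, y, covars, rescov = inp$rescov,
        estimator = cfg$estimators[["edge"]], gfit = gfit,
        cohort_id = id, weighting = w, scale = "edge")
      if (cfg$moderation) {
        if (sd(covars$age) >= 3) {
          mod[[paste0("g", w)]] <- netg_assoc_batch(
            gmat, y, covars, rescov = inp$rescov, estimator = "fs",
            gfit = gfit, moderation = TRUE, cohort_id = id, weighting = w,
            scale = "global")
          mod[[paste0("n", w)]] <- netg_assoc_batch(
            lmat, y, covars, rescov = inp$rescov, estimator = "fs",
            gfit = gfit, moderation = TRUE, cohort_id = id, weighting = w,
            scale = "node")
        } else {
          mod[[paste0("g", w)]] <- assoc_row(id, w, "global",
                                             colnames(gmat), NA_real_,
                                             NA_real_, length(use),
                                             flag = "skipped_narrow_age")
          mod[[paste0("n", w)]] <- assoc_row(id, w, "node",
                                             colnames(lmat), NA_real_,
                                             NA_real_, length(use),
                                             flag = "skipped_narrow_age")
        }
      }
    }
    assoc <- do.call(rbind, out)
    assoc$beta <- signif(assoc$beta, 10)
    assoc$se <- signif(assoc$se, 10)
    assoc[, c("ci_lo", "ci_hi", "p")] <-
      signif(assoc[, c("ci_lo", "ci_hi", "p")], 10)
    fwrite_(assoc, file.path(out_dir, id, "associations.csv"))
    if (cfg$moderation) {
      mdf <- do.call(rbind, mod)
      mdf[, c("beta", "se", "ci_lo", "ci_hi", "p")] <-
        signif(mdf[, c("beta", "se", "ci_lo", "ci_hi", "p")], 10)
      fwrite_(mdf, file.path(out_dir, id, "moderation.csv"))
    }
    info[[id]] <- list(rows = nrow(assoc),
                       moderation = if (cfg$moderation)
                         !all(mod[[1]]$flag == "skipped_narrow_age")
                       else NA)
    stage_log(NULL, "associate", sprintf("%s: %d rows", id, nrow(assoc)))
  }
  info
}

stage_meta <- function(cfg, out_dir) {
  cids <- names(cfg$sim$cohorts)
  tabs <- lapply(cids, function(id)
    fread_(file.path(out_dir, id, "associations.csv")))
  res <- meta_batch(tabs, q = cfg$fdr_q)
  num <- c("beta_meta", "se_meta", "ci_lo", "ci_hi", "p", "tau2", "q_value")
  res[num] <- lapply(res[num], signif, 10)
  fwrite_(res, file.path(out_dir, "meta.csv"))
  stage_log(NULL, "meta", sprintf("%d metrics pooled, %d significant",
                                  nrow(res), sum(res$significant, na.rm = TRUE)))
  list(rows = nrow(res), significant = sum(res$significant, na.rm = TRUE))
}

stage_predict <- function(cfg, out_dir, cids, wts) {
  ref <- read_edge_mask(file.path(out_dir, "reference_mask.csv"))
  rows <- mask_rows(ref)
  meta <- fread_(file.path(out_dir, "meta.csv"))
  out <- list()
  for (w in wts) {
    betas <- meta$beta_meta[meta$scale == "edge" & meta$weighting == w]
    betas[!is.finite(betas)] <- 0
    for (id in cids) {
      E <- read_edge_csv(file.path(out_dir, id, paste0("edges_", w, ".csv")))[, rows, drop = FALSE]
      gs <- fread_(file.path(out_dir, id, "gscores.csv"))$g
      n <- nrow(E)
      use <- main_rows(cfg, id, n)
      ho <- holdout_rows(cfg, id, n)
      tr_center <- colMeans(E[use, , drop = FALSE])
      tr_scale <- apply(E[use, , drop = FALSE], 2, sd)
      sc_main <- suppressWarnings(composite_scores(E[use, , drop = FALSE], betas))
      r_main <- cor(sc_main, gs[use], use = "complete.obs")
      out[[paste0(w, "_", id, "_train")]] <-
        data.frame(weighting = w, sample = paste0(id, "_main"),
                   r = signif(r_main, 10), n = length(use))
      if (length(ho)) {
        sc_ho <- if (cfg$standardization == "train")
          suppressWarnings(composite_scores(E[ho, , drop = FALSE], betas,
                                            center = tr_center,
                                            scale = tr_scale))
        else suppressWarnings(composite_scores(E[ho, , drop = FALSE], betas))
        r_ho <- cor(sc_ho, gs[ho], use = "complete.obs")
        out[[paste0(w, "_", id, "_holdout")]] <-
          data.frame(weighting = w, sample = paste0(id, "_holdout"),
                     r = signif(r_ho, 10), n = length(ho))
      }
    }
  }
  pred <- do.call(rbind, out)
  rownames(pred) <- NULL
  fwrite_(pred, file.path(out_dir, "prediction.csv"))
  stage_log(NULL, "predict", sprintf("%d sample x weighting correlations",
                                     nrow(pred)))
  list(rows = nrow(pred))
}

stage_report <- function(cfg, out_dir, cids, wts) {
  ref <- read_edge_mask(file.path(out_dir, "reference_mask.csv"))
  cls <- classify_edges(ref)
  fwrite_(cls$hemisphere_table, file.path(out_dir, "edge_hemisphere.csv"))
  fwrite_(cls$lobe_table, file.path(out_dir, "edge_lobe.csv"))
  lp <- as.data.frame(cls$lobe_pair_counts)
  lp <- cbind(lobe = rownames(cls$lobe_pair_counts), lp)
  fwrite_(lp, file.path(out_dir, "edge_lobe_pairs.csv"))

  meta <- fread_(file.path(out_dir, "meta.csv"))
  tabs <- lapply(cids, function(id)
    fread_(file.path(out_dir, id, "associations.csv")))
  agree <- list()
  for (w in wts) for (sc in c("node", "edge")) {
    pairs <- utils::combn(seq_along(cids), 2)
    for (k in seq_len(ncol(pairs))) {
      a <- pairs[1, k]; b <- pairs[2, k]
      va <- tabs[[a]]$beta[tabs[[a]]$scale == sc & tabs[[a]]$weighting == w]
      vb <- tabs[[b]]$beta[tabs[[b]]$scale == sc & tabs[[b]]$weighting == w]
      agree[[length(agree) + 1]] <-
        data.frame(weighting = w, scale = sc, cohort_a = cids[a],
                   cohort_b = cids[b],
                   r = signif(tryCatch(beta_agreement(va, vb),
                                       error = function(e) NA_real_), 10))
    }
  }
  fwrite_(do.call(rbind, agree), file.path(out_dir, "agreement.csv"))

  sym <- lapply(wts, function(w) {
    nb <- meta$beta_meta[meta$scale == "node" & meta$weighting == w]
    data.frame(weighting = w,
               r = signif(tryCatch(hemispheric_symmetry(nb),
                                   error = function(e) NA_real_), 10))
  })
  fwrite_(do.call(rbind, sym), file.path(out_dir, "symmetry.csv"))
  stage_log(NULL, "report", "classification, agreement, symmetry written")
  list(reference_edges = nrow(ref),
       intra_hemispheric_pct =
         cls$hemisphere_table$pct[cls$hemisphere_table$category == "intra_hemispheric"])
}
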