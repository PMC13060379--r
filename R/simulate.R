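# Multi-cohort synthetic data with the statistical structure the analysis
# assumes: three cohorts of distinct size, age range and site structure;
# cohort-specific network density and weight scale; a latent g generating
# test scores through loadings in a realistic range; network-g effects at
# the global and edge level with optional age moderation; age effects on
# FA/MD; and a streamline-count total strongly correlated with total brain
# volume. Networks are generated on a distance-dependent group template
# over synthetic node geometry — no attempt is made to simulate
# tractography or real anatomy.

# deterministic seed derivation: one root seed expanded per cohort/stage
derive_seed <- function(root, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(root) * 48271 + h) %% (2^31 - 1))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic pseudo-anatomical node coordinates: lobe centroids plus
# golden-ratio offsets, mirrored across hemispheres
node_coords <- function() {
  atlas <- dk_atlas()
  cent <- rbind(frontal = c(1.2, 0.6), parietal = c(-0.6, 0.9),
                temporal = c(0.2, -0.5), occipital = c(-1.4, 0.1),
                cingulate = c(0.2, 0.4), insula = c(0.4, 0.0),
                subcortical = c(0.0, -0.1), brainstem = c(-0.3, -0.9))
  phi <- (sqrt(5) - 1) / 2
  k <- atlas$index
  off1 <- ((k + 1) * phi) %% 1 - 0.5
  off2 <- ((k + 1) * phi * phi) %% 1 - 0.5
  x <- ifelse(atlas$hemisphere == "left", -1, ifelse(atlas$hemisphere == "right", 1, 0))
  x <- x * (0.6 + 0.35 * abs(off1)) * ifelse(atlas$lobe == "subcortical", 0.4, 1)
  cbind(x = x,
        y = cent[atlas$lobe, 1] + 0.8 * off1,
        z = cent[atlas$lobe, 2] + 0.8 * off2)
}

#' Configuration for the synthetic multi-cohort generator
#'
#' Returns the default simulation configuration, a nested list that can be
#' partially overridden through `...` (top-level elements replaced by
#' name). The defaults emulate the study conditions the pipeline targets:
#' a large wide-age four-site cohort, a small wide-age two-site cohort and
#' a small narrow-age single-site cohort, with cohort network densities
#' 0.35/0.32/0.30, factor loadings spanning 0.28-0.73, 10% missing test
#' scores, a global SC-g effect of 0.18 (FA 0.13, MD -0.08), age
#' moderation of the FA/MD effects (+0.017 / -0.045 per SD age),
#' edge-level effects realised as per-edge modulation of the global
#' effect (SD 50%, plus an optional sparse `beta_edge_map` of independent
#' per-edge effects), and an SC-TBV correlation target of 0.80.
#'
#' @param seed root seed; every stage derives its own stream from it.
#' @param ... top-level overrides (e.g. `cohorts = ...`, `effects = ...`).
#' @return a list of class `netcog_sim_config`.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    cohorts = list(
      cohort_a = list(n = 2000, age_range = c(45, 83), n_sites = 4,
                      density_target = 0.35, weight_scale = 1.0,
                      n_tests = 10, rescov = NULL),
      cohort_b = list(n = 500, age_range = c(26, 84), n_sites = 2,
                      density_target = 0.32, weight_scale = 0.9,
                      n_tests = 5, rescov = list(c(1, 5))),
      cohort_c = list(n = 400, age_range = c(71, 74), n_sites = 1,
                      density_target = 0.30, weight_scale = 0.8,
                      n_tests = 13,
                      rescov = list(c(1, 2), c(3, 4), c(5, 6), c(7, 8)))),
    loading_range = c(0.28, 0.73),
    missing_rate = 0.10,
    rescov_rho = 0.15,
    effects = list(
      beta_global = c(SC = 0.18, FA = 0.13, MD = -0.08),
      beta_age_moderation = c(SC = 0, FA = 0.017, MD = -0.045),
      edge_mod_sd = 0.5,
      beta_edge_map = NULL),
    sc_tbv_corr_target = 0.80,
    noise = list(weight_jitter_sd = 0.5, sc_kappa = 0.25,
                 fa_kappa = 0.02, md_kappa = 0.03,
                 fa_age_slope = -0.015, md_age_slope = 0.025,
                 fa_edge_noise = 0.03, md_edge_noise = 0.04,
                 cohort_template_sd = 0.5))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  if (abs(cfg$sc_tbv_corr_target) >= 1)
    stop("infeasible correlation target (|r| >= 1)")
  class(cfg) <- "netcog_sim_config"
  cfg
}

# shared edge-level template: distance, SC/FA/MD baselines, and the fixed
# per-edge g-sensitivity map that generates diffuse edge effects
sim_template <- function(cfg, n_nodes = 85L) {
  xyz <- node_coords()
  et <- all_edges(n_nodes)
  d <- sqrt(rowSums((xyz[et$i + 1L, ] - xyz[et$j + 1L, ])^2))
  dn <- d / max(d)
  with_seed(derive_seed(cfg$seed, "template"), {
    list(d = dn,
         logit_p = 2.2 - 7.5 * dn,
         log_w = 5.5 - 3.0 * dn + rnorm(length(dn), 0, 0.3),
         fa_base = pmin(pmax(0.55 - 0.25 * dn + rnorm(length(dn), 0, 0.03), 0.2), 0.7),
         md_base = pmin(pmax(0.70 + 0.30 * dn + rnorm(length(dn), 0, 0.04), 0.6), 1.2),
         edge_u = rnorm(length(dn)))
  })
}

#' Generate one synthetic cohort
#'
#' Draws a cohort of participants with covariates (age, sex, site, total
#' brain volume), a latent g and a battery of test scores with MCAR
#' missingness, and SC/FA/MD networks built from a distance-dependent
#' log-normal group template: edge presence is Bernoulli per participant
#' with cohort-calibrated probabilities, weights carry log-normal jitter,
#' and g enters through a global weight multiplier, per-edge sensitivities
#' and (for FA/MD) participant-level shifts, with an age-interaction term.
#' FA and MD are zero wherever SC is zero. Identical seeds give
#' bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @param cohort_id name of the cohort block in `cfg$cohorts`.
#' @param weightings subset of `c("SC","FA","MD")` to generate.
#' @param edge_rows optional integer rows of [all_edges()] to generate
#'   (defaults to all 3570 pairs); useful at very large n.
#' @return list with `covars` (data.frame: participant_id, age, sex, site,
#'   tbv, true_g), `tests` (matrix with NA), `networks` (named list of
#'   participants x pairs edge matrices), `node_volumes` (participants x
#'   85), `loadings` and `rescov` (the generating battery), and
#'   `edge_rows`.
#' @export
simulate_cohort <- function(cfg, cohort_id, weightings = c("SC", "FA", "MD"),
                            edge_rows = NULL) {
  cc <- cfg$cohorts[[cohort_id]]
  if (is.null(cc)) stop("unknown cohort id: ", cohort_id)
  if (cc$n < 10 * cc$n_sites)
    stop("n too small for the requested number of sites")
  tpl <- sim_template(cfg)
  et <- all_edges()
  if (is.null(edge_rows)) edge_rows <- seq_len(nrow(et))
  ne <- length(edge_rows)
  n <- cc$n
  nz <- cfg$noise
  eff <- cfg$effects

  with_seed(derive_seed(cfg$seed, paste0("cohort:", cohort_id)), {
    # cohort-level template perturbation, recalibrated to the density target
    zc <- rnorm(nrow(et), 0, nz$cohort_template_sd)
    a <- uniroot(function(a) mean(plogis(tpl$logit_p + zc + a)) - cc$density_target,
                 c(-20, 20))$root
    pe <- plogis(tpl$logit_p + zc + a)[edge_rows]

    age <- runif(n, cc$age_range[1], cc$age_range[2])
    age_z <- as.numeric(scale(age))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    site <- paste0("site", sample.int(cc$n_sites, n, replace = TRUE))
    site_shift <- rnorm(cc$n_sites, 0, 0.05)[as.integer(sub("site", "", site))]
    g <- rnorm(n)

    # participant-level drivers per weighting: cor(driver, g) equals the
    # (age-moderated) global effect by construction
    driver <- function(beta, mod) {
      b <- beta + mod * age_z
      b * g + sqrt(pmax(1 - beta^2, 0)) * rnorm(n)
    }
    t_sc <- driver(eff$beta_global["SC"], eff$beta_age_moderation["SC"])
    t_fa <- driver(eff$beta_global["FA"], eff$beta_age_moderation["FA"])
    t_md <- driver(eff$beta_global["MD"], eff$beta_age_moderation["MD"])

    present <- matrix(rbinom(n * ne, 1L, rep(pe, each = n)), n, ne)
    ids <- sprintf("%s_p%04d", cohort_id, seq_len(n))

    # per-edge sensitivity to the shared g-driver: edge-level effects are
    # mostly redundant modulations of the global effect (heterogeneous in
    # size, mostly consistent in sign), which keeps composite prediction in
    # a realistic range rather than compounding hundreds of independent
    # signals; an explicit sparse beta_edge_map adds independent per-edge
    # effects on top (scaled by the edge noise so the map value is roughly
    # the target edge-g correlation)
    esens <- 1 + eff$edge_mod_sd * tpl$edge_u[edge_rows]
    emap <- numeric(ne)
    if (!is.null(eff$beta_edge_map) && length(eff$beta_edge_map)) {
      at <- match(as.integer(names(eff$beta_edge_map)), edge_rows)
      emap[at[!is.na(at)]] <- unlist(eff$beta_edge_map)[!is.na(at)]
    }
    networks <- list()
    logw <- matrix(rep(tpl$log_w[edge_rows], each = n), n, ne) +
      matrix(rnorm(n * ne, 0, nz$weight_jitter_sd), n, ne) +
      nz$sc_kappa * t_sc %o% esens + site_shift + log(cc$weight_scale) +
      nz$weight_jitter_sd * g %o% emap
    SC <- round(exp(logw)) * present
    if ("SC" %in% weightings) {
      networks$SC <- SC
      rownames(networks$SC) <- ids
    }
    if ("FA" %in% weightings) {
      FA <- matrix(rep(tpl$fa_base[edge_rows], each = n), n, ne) +
        matrix(rnorm(n * ne, 0, nz$fa_edge_noise), n, ne) +
        nz$fa_age_slope * age_z + nz$fa_kappa * t_fa %o% esens +
        nz$fa_edge_noise * g %o% emap
      FA <- pmin(pmax(FA, 0.05), 0.95) * present * (SC > 0)
      networks$FA <- FA
      rownames(networks$FA) <- ids
    }
    if ("MD" %in% weightings) {
      MD <- matrix(rep(tpl$md_base[edge_rows], each = n), n, ne) +
        matrix(rnorm(n * ne, 0, nz$md_edge_noise), n, ne) +
        nz$md_age_slope * age_z + nz$md_kappa * t_md %o% esens +
        nz$md_edge_noise * g %o% emap
      MD <- pmin(pmax(MD, 0.3), 1.5) * present * (SC > 0)
      networks$MD <- MD
      rownames(networks$MD) <- ids
    }

    # total brain volume built to hit the SC-total correlation target
    r <- cfg$sc_tbv_corr_target
    tot <- rowSums(SC)
    tbv <- 1.2e6 * exp(0.1 * (r * as.numeric(scale(tot)) +
                              sqrt(1 - r^2) * rnorm(n)))
    vol_base <- 4000 + 120 * (0:84)
    node_volumes <- exp(matrix(rnorm(n * 85, 0, 0.05), n, 85)) *
      (tbv / mean(tbv)) %o% vol_base
    rownames(node_volumes) <- ids

    # test battery: loadings span the configured range; residual
    # covariances realised through shared pair components
    p <- cc$n_tests
    lambda <- seq(cfg$loading_range[1], cfg$loading_range[2], length.out = p)
    theta <- 1 - lambda^2
    rescov <- cc$rescov
    eps <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(theta))
    if (length(rescov)) {
      for (pr in rescov) {
        a_i <- pr[1]; b_i <- pr[2]
        cv <- cfg$rescov_rho * sqrt(theta[a_i] * theta[b_i])
        shared <- rnorm(n, 0, sqrt(cv))
        eps[, a_i] <- sqrt((theta[a_i] - cv) / theta[a_i]) * eps[, a_i] + shared
        eps[, b_i] <- sqrt((theta[b_i] - cv) / theta[b_i]) * eps[, b_i] + shared
      }
    }
    tests <- outer(g, lambda) + eps
    tests[matrix(runif(n * p) < cfg$missing_rate, n, p)] <- NA
    colnames(tests) <- sprintf("test%02d", seq_len(p))
    rownames(tests) <- ids

    list(covars = data.frame(participant_id = ids, age = age, sex = sex,
                             site = site, tbv = tbv, true_g = g,
                             stringsAsFactors = FALSE),
         tests = tests, networks = networks, node_volumes = node_volumes,
         loadings = lambda, rescov = rescov, edge_rows = edge_rows)
  })
}

#' Generate the default three-cohort dataset
#'
#' Applies [simulate_cohort()] to every cohort block of the configuration
#' (by default: large/wide-age/4-site, small/wide-age/2-site,
#' small/narrow-age/1-site).
#'
#' @inheritParams simulate_cohort
#' @return named list of cohorts as returned by [simulate_cohort()].
#' @export
simulate_cohorts <- function(cfg = sim_config(),
                             weightings = c("SC", "FA", "MD")) {
  setNames(lapply(names(cfg$cohorts), function(id)
    simulate_cohort(cfg, id, weightings = weightings)),
    names(cfg$cohorts))
}
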