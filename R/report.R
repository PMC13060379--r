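# Edge-wise composite prediction of g, cross-cohort agreement, hemispheric
# symmetry, edge classification by hemisphere/lobe, and spatial correlation
# with external regional maps.

#' Composite network score from meta-analytic edge weights
#'
#' Standardises every edge column within the evaluated sample (column
#' z-scores) and forms the weighted sum `sum_k beta_k * z_k` per
#' participant — the bivariate composite used to predict g. Zero-variance
#' columns are dropped with a warning. A strict out-of-sample variant uses
#' the means and SDs of a training sample for the standardisation.
#'
#' @param edges participants x edges numeric matrix, columns aligned with
#'   the weight vector (typically the reference-mask edge order).
#' @param weights numeric vector of meta-analytic coefficients, one per
#'   column.
#' @param center,scale optional training-sample column means and SDs for
#'   strict out-of-sample standardisation; by default the evaluated
#'   sample's own moments are used.
#' @return numeric vector of composite scores (named by participant when
#'   the matrix has rownames).
#' @export
composite_scores <- function(edges, weights, center = NULL, scale = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != length(weights))
    stop("one weight per edge column required")
  if (all(weights == 0)) warning("all edge weights are zero")
  if (is.null(center)) center <- colMeans(edges)
  if (is.null(scale)) scale <- apply(edges, 2, sd)
  keep <- is.finite(scale) & scale > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance edge column(s) dropped")
  Z <- sweep(sweep(edges[, keep, drop = FALSE], 2, center[keep]), 2,
             scale[keep], "/")
  out <- as.numeric(Z %*% weights[keep])
  names(out) <- rownames(edges)
  out
}

#' Cross-cohort agreement of coefficient vectors
#'
#' Pearson correlation between two aligned coefficient vectors (e.g. the
#' node-level betas of two cohorts). Pairs with missing entries are
#' dropped.
#'
#' @param a,b equal-length numeric vectors (>= 3 usable pairs).
#' @return Pearson r.
#' @export
beta_agreement <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("fewer than 3 usable pairs")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) stop("zero-variance input")
  cor(a[ok], b[ok])
}

#' Hemispheric symmetry of nodal coefficients
#'
#' Correlates the coefficients of the 42 left-hemisphere nodes with those
#' of their right homologues (bilateral pairs from the atlas); the
#' brainstem, the only midline node, is excluded.
#'
#' @param node_betas numeric vector of length 85 in atlas node order.
#' @param atlas atlas table (defaults to the packaged one).
#' @return Pearson r over the 42 homologue pairs.
#' @export
hemispheric_symmetry <- function(node_betas, atlas = dk_atlas()) {
  if (length(node_betas) != nrow(atlas))
    stop("one coefficient per atlas node required")
  left <- atlas[atlas$hemisphere == "left", ]
  right <- atlas[atlas$hemisphere == "right", ]
  right <- right[match(left$pair_index, right$pair_index), ]
  beta_agreement(node_betas[left$index + 1L], node_betas[right$index + 1L])
}

# percentage of a total to one decimal, round-half-even
pct1 <- function(x, total) round(100 * x / total, 1)

#' Classify reference-network edges by hemisphere and lobe
#'
#' Labels every mask edge as intra-left, intra-right, inter-hemispheric or
#' brainstem-involved, and as intra- or inter-lobar, and tabulates counts
#' with percentages of the mask size (one decimal place). On the published
#' 818-edge reference network with 647 intra- and 166 inter-hemispheric
#' edges this arithmetic gives 79.1% and 20.3%.
#'
#' @param mask an `edge_mask`.
#' @param atlas atlas table.
#' @return list with `edges` (per-edge categories), `hemisphere_table`,
#'   `lobe_table` and `lobe_pair_counts` (symmetric lobe x lobe matrix).
#' @export
classify_edges <- function(mask, atlas = dk_atlas()) {
  hi <- atlas$hemisphere[mask$i + 1L]
  hj <- atlas$hemisphere[mask$j + 1L]
  li <- atlas$lobe[mask$i + 1L]
  lj <- atlas$lobe[mask$j + 1L]
  hemi <- ifelse(hi == "midline" | hj == "midline", "brainstem_involved",
          ifelse(hi != hj, "inter",
          ifelse(hi == "left", "intra_left", "intra_right")))
  lobar <- ifelse(li == lj, "intra_lobe", "inter_lobe")
  edges <- data.frame(i = mask$i, j = mask$j, hemisphere = hemi,
                      lobar = lobar,
                      lobe_pair = paste(pmin(li, lj), pmax(li, lj), sep = "-"),
                      stringsAsFactors = FALSE)
  total <- nrow(mask)
  hcnt <- table(factor(hemi, levels = c("intra_left", "intra_right",
                                        "inter", "brainstem_involved")))
  htab <- data.frame(category = names(hcnt), count = as.integer(hcnt),
                     pct = pct1(as.integer(hcnt), total))
  htab <- rbind(htab,
                data.frame(category = "intra_hemispheric",
                           count = sum(hcnt[c("intra_left", "intra_right")]),
                           pct = pct1(sum(hcnt[c("intra_left", "intra_right")]), total)))
  lcnt <- table(factor(lobar, levels = c("intra_lobe", "inter_lobe")))
  ltab <- data.frame(category = names(lcnt), count = as.integer(lcnt),
                     pct = pct1(as.integer(lcnt), total))
  lobes <- sort(unique(atlas$lobe))
  lp <- matrix(0L, length(lobes), length(lobes),
               dimnames = list(lobes, lobes))
  for (r in seq_len(total)) {
    a <- li[r]; b <- lj[r]
    lp[a, b] <- lp[a, b] + 1L
    if (a != b) lp[b, a] <- lp[b, a] + 1L
  }
  list(edges = edges, hemisphere_table = htab, lobe_table = ltab,
       lobe_pair_counts = lp)
}

#' Correlate nodal coefficients with an external regional map
#'
#' Matches an externally supplied regional map (e.g. cortex-g coefficients
#' from a morphometry study over the 68 cortical regions) to the atlas by
#' region name and returns the Pearson correlation with the nodal
#' coefficients over the matched regions. Unmatched regions are reported
#' in the result's attributes.
#'
#' @param node_betas numeric vector of length 85 in atlas node order.
#' @param external_map data.frame with columns `region` (atlas names) and
#'   `value`.
#' @param atlas atlas table.
#' @return Pearson r with attributes `n_matched` and `unmatched`.
#' @export
map_correlation <- function(node_betas, external_map, atlas = dk_atlas()) {
  if (length(node_betas) != nrow(atlas))
    stop("one coefficient per atlas node required")
  idx <- match(external_map$region, atlas$name)
  matched <- !is.na(idx)
  if (sum(matched) < 3) stop("fewer than 3 regions matched to the atlas")
  r <- beta_agreement(node_betas[idx[matched]],
                      external_map$value[matched])
  attr(r, "n_matched") <- sum(matched)
  attr(r, "unmatched") <- external_map$region[!matched]
  r
}
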