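# Reference-network construction: per-cohort consistency thresholding to a
# target density, then cross-cohort mask intersection.

# Coerce a cohort's networks to a participants x 3570 edge matrix in
# canonical edge order. Accepts a list of connectomes or an existing matrix
# whose columns already follow all_edges().
as_edge_matrix <- function(stack, n_nodes = 85L) {
  if (is.matrix(stack)) {
    if (ncol(stack) != nrow(all_edges(n_nodes)))
      stop("edge matrix must have one column per node pair")
    return(stack)
  }
  et <- all_edges(n_nodes)
  out <- t(vapply(stack, function(W) as.numeric(unclass(W))[et$lin],
                  numeric(nrow(et))))
  rownames(out) <- vapply(stack, function(W) attr(W, "participant_id"), "")
  out
}

#' Edge-wise consistency statistics across participants
#'
#' For every node pair, the mean and standard deviation of the (streamline
#' count) weight across participants and their ratio, the coefficient of
#' variation (CV) — the consistency statistic used for thresholding. By
#' default participants with zero weight on an edge are included in the mean
#' and SD (an absent connection is zero streamlines); excluding them would
#' bias rare edges toward apparent consistency.
#'
#' @param stack list of SC `connectome`s from one cohort, or a participants
#'   x pairs edge matrix in canonical order.
#' @param zeros `"include"` (default) or `"exclude"`: whether zero weights
#'   enter the per-edge mean/SD.
#' @param n_nodes atlas size.
#' @return data.frame over all node pairs with columns `i`, `j`,
#'   `mean_weight`, `sd_weight`, `cv` (NA where the mean is zero) and
#'   `n_nonzero`.
#' @export
consistency_table <- function(stack, zeros = c("include", "exclude"),
                              n_nodes = 85L) {
  zeros <- match.arg(zeros)
  E <- as_edge_matrix(stack, n_nodes)
  if (nrow(E) < 2) stop("at least two participants required")
  et <- all_edges(n_nodes)
  if (zeros == "include") {
    mu <- colMeans(E)
    sdv <- apply(E, 2, sd)
  } else {
    mu <- apply(E, 2, function(x) if (any(x > 0)) mean(x[x > 0]) else 0)
    sdv <- apply(E, 2, function(x) if (sum(x > 0) > 1) sd(x[x > 0]) else NA_real_)
  }
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  data.frame(i = et$i, j = et$j, mean_weight = mu, sd_weight = sdv, cv = cv,
             n_nonzero = colSums(E > 0))
}

#' Consistency-threshold a cohort to a target network density
#'
#' Retains the `K = round(density * n_pairs)` node pairs with the lowest
#' coefficient of variation of weight across participants. Edges with zero
#' mean weight are excluded before ranking; ties are broken by higher mean
#' weight, then lexicographically by `(i, j)`.
#'
#' @inheritParams consistency_table
#' @param density target network density in `(0, 1]`. At 0.30 on an 85-node
#'   atlas this retains exactly 1071 of the 3570 pairs.
#' @return an `edge_mask` of exactly `K` edges.
#' @export
consistency_threshold <- function(stack, density, zeros = "include",
                                  n_nodes = 85L) {
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop("density must be in (0, 1]")
  tab <- consistency_table(stack, zeros = zeros, n_nodes = n_nodes)
  K <- round(density * nrow(tab))
  elig <- tab[!is.na(tab$cv), , drop = FALSE]
  if (nrow(elig) < K)
    stop(sprintf("only %d eligible edges for K = %d", nrow(elig), K))
  ord <- order(elig$cv, -elig$mean_weight, elig$i, elig$j)
  keep <- elig[ord[seq_len(K)], ]
  edge_mask(keep$i, keep$j, n_nodes = n_nodes,
            provenance = sprintf("consistency threshold, density %.4g, K=%d",
                                 density, K))
}

#' Intersect cohort edge masks
#'
#' Set intersection of two or more masks (the cross-cohort reference
#' network). The result's provenance records input sizes; pairwise overlap
#' counts are attached as attribute `"pairwise_overlap"`.
#'
#' @param masks list of `edge_mask` objects over the same atlas.
#' @return an `edge_mask`.
#' @export
intersect_masks <- function(masks) {
  if (length(masks) < 2) stop("need at least two masks")
  n <- attr(masks[[1]], "n_nodes")
  if (!all(vapply(masks, function(m) attr(m, "n_nodes"), 0L) == n))
    stop("masks are over different atlases")
  keys <- lapply(masks, function(m) paste(m$i, m$j))
  common <- Reduce(intersect, keys)
  k <- length(masks)
  ov <- matrix(NA_integer_, k, k)
  for (a in seq_len(k)) for (b in seq_len(k))
    ov[a, b] <- length(intersect(keys[[a]], keys[[b]]))
  base <- masks[[1]]
  sel <- base[paste(base$i, base$j) %in% common, , drop = FALSE]
  out <- edge_mask(sel$i, sel$j, n_nodes = n,
                   provenance = sprintf("intersection of %d masks (sizes %s)",
                                        k, paste(vapply(masks, nrow, 0L),
                                                 collapse = "/")))
  attr(out, "pairwise_overlap") <- ov
  out
}
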