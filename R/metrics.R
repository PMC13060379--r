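# Weighted graph metrics. Lengths are reciprocal weights (l = 1/w) for all
# weightings, including MD: the networks are analysed on their raw weights,
# with no inversion of MD. Clustering and local efficiency use weights
# max-normalised per participant (standard for the Onnela form); global
# efficiency uses raw weights.

#' Mean edge weight over a reference network
#'
#' Mean of the connectome's weights across the mask's edge set, zeros
#' included (an absent connection counts as weight 0).
#'
#' @param c a `connectome` or symmetric matrix.
#' @param m an `edge_mask`; if omitted, all node pairs.
#' @return a scalar.
#' @export
mean_edge_weight <- function(c, m = NULL) {
  W <- unclass(c)
  if (is.null(m)) return(mean(W[upper.tri(W)]))
  if (nrow(m) == 0) stop("empty mask")
  mean(W[all_edges(nrow(W))$lin[mask_rows(m)]])
}

#' Weighted global efficiency
#'
#' Average inverse shortest weighted path length over all ordered node
#' pairs, with edge lengths `1/w` and unreachable pairs contributing zero.
#' A measure of network integration; 1 for a complete unit-weight graph.
#'
#' @param W symmetric nonnegative weight matrix.
#' @return a scalar `>= 0`.
#' @export
global_efficiency <- function(W) {
  W <- unclass(W)
  n <- nrow(W)
  if (n < 2) return(0)
  D <- sp_dist(W)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean weighted clustering coefficient (Onnela)
#'
#' Weights are max-normalised, each node's coefficient is the sum of
#' geometric-mean triangle intensities `(w_ij w_ih w_jh)^(1/3)` divided by
#' `k_i (k_i - 1)` (binary degree), zero for degree < 2, and the mean over
#' all nodes is returned. A segregation measure in `[0, 1]`.
#'
#' @param W symmetric nonnegative weight matrix.
#' @return a scalar in `[0, 1]`.
#' @export
mean_clustering <- function(W) {
  W <- unclass(W)
  mx <- max(W)
  if (mx <= 0) return(0)
  Wn <- W / mx
  K <- Wn^(1 / 3)
  num <- diag(K %*% K %*% K)       # sum over ordered (j, h) triangle pairs
  k <- rowSums(W > 0)
  ci <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  mean(ci)
}

#' Weighted local efficiency per node
#'
#' For each node, the efficiency of communication within its immediate
#' neighbourhood: shortest paths between each pair of neighbours are
#' computed within the subgraph induced by the neighbour set (lengths
#' `1/w` on max-normalised weights) and combined as
#' `(w_ij w_ih / d_jh)^(1/3)`, averaged over ordered neighbour pairs.
#' Nodes with fewer than two neighbours score 0.
#'
#' @param W symmetric nonnegative weight matrix.
#' @return numeric vector, one value per node.
#' @export
local_efficiency <- function(W) {
  W <- unclass(W)
  mx <- max(W)
  if (mx <= 0) return(numeric(nrow(W)))
  as.numeric(local_eff_w(W / mx))
}

#' Graph metrics for a cohort of networks
#'
#' Applies the mask and computes the three global metrics (mean edge
#' weight, global efficiency, mean clustering) and nodal local efficiency
#' for every participant.
#'
#' @param stack list of `connectome`s, or a participants x pairs edge
#'   matrix in canonical order (see [all_edges()]).
#' @param mask an `edge_mask` applied before computing metrics.
#' @param weighting label copied into the output.
#' @param n_nodes atlas size.
#' @return list with `global` (data.frame: participant_id, weighting,
#'   mean_edge_weight, global_efficiency, mean_clustering) and `local`
#'   (participants x nodes matrix of local efficiency).
#' @export
network_metrics <- function(stack, mask, weighting = "SC", n_nodes = 85L) {
  E <- as_edge_matrix(stack, n_nodes)
  rows <- mask_rows(mask)
  lin <- all_edges(n_nodes)$lin
  np <- nrow(E)
  ids <- rownames(E)
  if (is.null(ids)) ids <- paste0("p", seq_len(np))
  glob <- matrix(0, np, 3)
  loc <- matrix(0, np, n_nodes)
  W <- matrix(0, n_nodes, n_nodes)
  for (r in seq_len(np)) {
    W[] <- 0
    W[lin[rows]] <- E[r, rows]
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    glob[r, 1] <- mean(E[r, rows])
    glob[r, 2] <- global_efficiency(W)
    glob[r, 3] <- mean_clustering(W)
    loc[r, ] <- local_efficiency(W)
  }
  rownames(loc) <- ids
  colnames(loc) <- dk_atlas()$name[seq_len(n_nodes)]
  list(global = data.frame(participant_id = ids, weighting = weighting,
                           mean_edge_weight = glob[, 1],
                           global_efficiency = glob[, 2],
                           mean_clustering = glob[, 3],
                           stringsAsFactors = FALSE),
       local = loc)
}
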