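#' Weighted degree (strength)
#'
#' The degree of a node is the sum of its edge weights to all other nodes.
#' Weights are summed as stored; apply [clip_negative_weights()] first if a
#' nonnegative degree is required for functional networks.
#'
#' @param net a [weighted_network].
#' @return Named numeric vector (one value per ROI).
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1
#' w[1, 3] <- w[3, 1] <- 2; w[2, 3] <- w[3, 2] <- 3
#' weighted_degree(weighted_network(w, letters[1:3], "structural"))  # 3 4 5
#' @export
weighted_degree <- function(net) {
  assert_network(net)
  rowSums(net$weights)
}

#' Segregation coefficient
#'
#' For each node, the ratio of its within-module strength to its total
#' strength, given a community partition: 1 means every connection stays
#' inside the node's own subnetwork, values near 0 mark connector hubs whose
#' weight mostly crosses module boundaries.  Isolated nodes (total strength
#' zero) have an undefined ratio and are returned as `NA`; downstream
#' permutation tests drop them.
#'
#' @param net a nonnegative [weighted_network].
#' @param partition a [community_partition] or a membership vector.
#' @return Named numeric vector in [0, 1], `NA` where undefined.
#' @export
segregation_coefficient <- function(net, partition) {
  assert_network(net)
  memb <- as_membership(partition, n_rois(net))
  w <- net$weights
  if (any(w < 0)) stop("segregation coefficient requires nonnegative weights")
  total <- rowSums(w)
  same <- outer(memb, memb, "==")
  intra <- rowSums(w * same)
  out <- ifelse(total > 0, intra / total, NA_real_)
  names(out) <- net$roi_labels
  out
}

# edge lengths = 1/weight, absent edge (w == 0) = no edge; Dijkstra via igraph
distance_matrix <- function(net) {
  w <- net$weights
  if (any(w < 0)) stop("path metrics require nonnegative weights")
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ew <- igraph::E(g)$weight
  igraph::distances(g, weights = 1 / ew, algorithm = "dijkstra")
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all ordered pairs of distinct nodes, with
#' edge lengths taken as the reciprocal of edge weight (strong connections are
#' short).  On disconnected networks the mean is taken over the finite pairs
#' and the number of unreachable ordered pairs is attached as attribute
#' `n_unreachable`.
#'
#' @param net a nonnegative [weighted_network].
#' @return A single number with attribute `n_unreachable`.
#' @export
characteristic_path_length <- function(net) {
  assert_network(net)
  d <- distance_matrix(net)
  d <- d[row(d) != col(d)]
  finite <- is.finite(d)
  if (!any(finite)) stop("network is fully disconnected: no finite path exists")
  structure(mean(d[finite]), n_unreachable = sum(!finite))
}

#' Global efficiency
#'
#' The default (`method = "mean_inverse"`) is the mean of the inverse
#' shortest-path distances over ordered pairs, with 1/Inf = 0 for unreachable
#' pairs -- the standard weighted-efficiency formula.  `method = "inverse_cpl"`
#' returns instead the literal reciprocal of the characteristic path length;
#' the two coincide only on very regular networks, and both are exposed
#' because the verbal definition of efficiency as "the inverse of the path
#' length" is common in the applied literature.
#'
#' @param net a nonnegative [weighted_network] with at least 2 nodes.
#' @param method `"mean_inverse"` (default) or `"inverse_cpl"`.
#' @return A single nonnegative number.
#' @export
global_efficiency <- function(net, method = c("mean_inverse", "inverse_cpl")) {
  assert_network(net)
  method <- match.arg(method)
  if (n_rois(net) < 2) stop("need at least 2 nodes")
  if (method == "inverse_cpl") return(1 / as.numeric(characteristic_path_length(net)))
  d <- distance_matrix(net)
  inv <- 1 / d[row(d) != col(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Local efficiency
#'
#' For each node, the global efficiency of the subgraph induced on its
#' neighbours (nodes connected to it with positive weight); nodes with fewer
#' than two neighbours contribute 0.  The result is the average over nodes.
#'
#' @param net a nonnegative [weighted_network] with at least 2 nodes.
#' @return A single nonnegative number.
#' @export
local_efficiency <- function(net) {
  assert_network(net)
  n <- n_rois(net)
  if (n < 2) stop("need at least 2 nodes")
  w <- net$weights
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- weighted_network(w[nb, nb, drop = FALSE], net$roi_labels[nb],
                            net$modality, net$band)
    global_efficiency(sub)
  }, numeric(1))
  mean(eff)
}

#' Density after removing the weakest edges
#'
#' Removes the weakest `ceiling(prune_fraction * E)` of the existing edges
#' (weight > 0; ties broken by stable node-index order), binarizes the rest,
#' and returns the fraction of possible edges present,
#' \eqn{2E' / (n(n-1))}.  The default 1% pruning discards spurious weakest
#' connections before counting.
#'
#' @param net a [weighted_network].
#' @param prune_fraction fraction of existing edges to remove, in [0, 1).
#' @return Density in [0, 1].
#' @export
density_after_pruning <- function(net, prune_fraction = 0.01) {
  assert_network(net)
  if (prune_fraction < 0 || prune_fraction >= 1)
    stop("'prune_fraction' must be in [0, 1)")
  n <- n_rois(net)
  ut <- which(upper.tri(net$weights))
  wvals <- net$weights[ut]
  idx <- which(wvals > 0)
  e <- length(idx)
  if (e == 0) return(0)
  n_drop <- ceiling(prune_fraction * e)
  # weakest first; ties broken by stable upper-triangle (node-index) order
  drop <- idx[order(wvals[idx], idx)][seq_len(n_drop)]
  kept <- e - length(drop)
  2 * kept / (n * (n - 1))
}

#' All global graph measures at once
#'
#' Convenience wrapper returning characteristic path length, global and local
#' efficiency, and pruned density for one network.
#'
#' @param net a nonnegative [weighted_network].
#' @param prune_fraction passed to [density_after_pruning()].
#' @return A list with elements `char_path_length`, `n_unreachable`,
#'   `global_efficiency`, `local_efficiency`, `density`.
#' @export
global_metrics <- function(net, prune_fraction = 0.01) {
  cpl <- characteristic_path_length(net)
  list(char_path_length = as.numeric(cpl),
       n_unreachable = attr(cpl, "n_unreachable"),
       global_efficiency = global_efficiency(net),
       local_efficiency = local_efficiency(net),
       density = density_after_pruning(net, prune_fraction))
}
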