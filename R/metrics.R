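#' Node degrees of a weighted network
#'
#' Degree of node `i` is the number of neighbours connected by a nonzero
#' weight.
#'
#' @param network A `coherence_network` or symmetric weight matrix.
#' @return Integer vector of degrees, named by node label.
#' @export
node_degrees <- function(network) {
  w <- net_weights(network)
  diag(w) <- 0
  k <- rowSums(w > 0)
  names(k) <- rownames(w)
  k
}

#' Weighted clustering coefficient (Onnela form)
#'
#' Per-node clustering
#' `C_i = sum_{j,h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))`, where `k_i`
#' is the node degree; `C_i = 0` when `k_i < 2`. The network value is the
#' average over all `N` nodes (nodes with fewer than two neighbours
#' contribute zero). Quantifies how strongly a node's direct neighbours
#' are interconnected.
#'
#' Coherence weights live on a natural `[0, 1]` scale, so they are used
#' as-is by default and `0 <= C_i <= 1` holds. `normalize = "max"`
#' instead rescales by the network's maximum weight, which makes the
#' coefficient a purely relative measure of weight heterogeneity and
#' discards the overall connectivity level.
#'
#' @param network A `coherence_network` or symmetric weight matrix with
#'   nonnegative weights (at most 1 unless `normalize = "max"`).
#' @param normalize `"none"` (default, weights already in `[0, 1]`) or
#'   `"max"` (divide by the network maximum).
#' @return List with `by_node` (per-node `C_i`) and `mean` (network `C`).
#' @export
clustering_coefficient <- function(network, normalize = c("none", "max")) {
  normalize <- match.arg(normalize)
  w <- net_weights(network)
  diag(w) <- 0
  if (min(w) < 0) stop("weights must be nonnegative")
  if (normalize == "none" && max(w) > 1 + 1e-9) {
    stop("weights exceed 1; rescale or use normalize = \"max\"")
  }
  k <- rowSums(w > 0)
  mx <- if (normalize == "max") max(w) else 1
  ci <- rep(0, nrow(w))
  if (max(w) > 0) {
    w3 <- (w / mx)^(1 / 3)
    tri <- diag(w3 %*% w3 %*% w3) # sums (w'_ij w'_jh w'_hi)^(1/3) over ordered j, h
    ok <- k >= 2
    ci[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  }
  names(ci) <- rownames(w)
  list(by_node = ci, mean = mean(ci))
}

#' All-pairs shortest path lengths over inverse-weight edge lengths
#'
#' The length of an edge is the inverse of its weight, `1 / w_ij` (strong
#' connections are short); absent edges have infinite length. Path lengths
#' are computed over nonnegative edge lengths for every node pair;
#' `L_ii = 0` and disconnected pairs are `Inf`.
#'
#' @param network A `coherence_network` or symmetric weight matrix.
#' @return Numeric matrix of shortest path lengths `L_ij`.
#' @export
shortest_path_lengths <- function(network) {
  w <- net_weights(network)
  diag(w) <- 0
  if (min(w) < 0) stop("weights must be nonnegative")
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) { # Floyd-Warshall; n is small (18 electrodes)
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  dimnames(d) <- dimnames(w)
  d
}

#' Characteristic path length (harmonic mean)
#'
#' `L = N(N-1) / sum_{i != j} 1 / L_ij`, the harmonic mean of all-pairs
#' shortest path lengths, with `1 / Inf = 0`: disconnected pairs simply
#' drop out of the sum, so the measure stays finite on fragmented
#' sub-networks. `L` is the exact inverse of the global efficiency.
#'
#' @param network A `coherence_network` or symmetric weight matrix with at
#'   least 2 nodes.
#' @return The characteristic path length; `NaN` with a warning when every
#'   pair is disconnected.
#' @export
characteristic_path_length <- function(network) {
  eg <- global_efficiency(network)
  if (eg == 0) {
    warning("all node pairs disconnected: characteristic path length undefined")
    return(NaN)
  }
  1 / eg
}

#' Global efficiency
#'
#' `E_glob = mean over i != j of 1 / L_ij`, the average inverse shortest
#' path length; disconnected pairs contribute zero. Measures the capacity
#' for parallel information transfer across the whole network.
#'
#' @param network A `coherence_network` or symmetric weight matrix with at
#'   least 2 nodes.
#' @return Global efficiency (0 for an empty network).
#' @export
global_efficiency <- function(network) {
  L <- shortest_path_lengths(network)
  n <- nrow(L)
  if (n < 2) stop("at least 2 nodes are required")
  inv <- 1 / L
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' `E_loc(i)` is the global efficiency of the subgraph induced by the
#' direct neighbours of node `i` (node `i` itself excluded, original
#' weights retained, paths confined to the subgraph); `E_loc(i) = 0` when
#' the node has fewer than two neighbours. The network value averages all
#' `N` nodes. Interpreted as fault tolerance: how efficiently the
#' neighbourhood communicates if the node is removed.
#'
#' @param network A `coherence_network` or symmetric weight matrix.
#' @return List with `by_node` and `mean`.
#' @export
local_efficiency <- function(network) {
  w <- net_weights(network)
  diag(w) <- 0
  el <- vapply(seq_len(nrow(w)), function(i) {
    nbr <- which(w[i, ] > 0)
    if (length(nbr) < 2) return(0)
    global_efficiency(w[nbr, nbr, drop = FALSE])
  }, numeric(1))
  names(el) <- rownames(w)
  list(by_node = el, mean = mean(el))
}

#' Mean functional connectivity of a network
#'
#' Arithmetic mean of the nonzero edge weights (the mean connection
#' strength among present edges).
#'
#' @param network A `coherence_network` or symmetric weight matrix.
#' @return Mean nonzero edge weight (`NaN` for an empty network).
#' @export
mean_connectivity <- function(network) {
  w <- net_weights(network)
  wt <- w[upper.tri(w)]
  wt <- wt[wt > 0]
  if (!length(wt)) return(NaN)
  mean(wt)
}

#' All weighted topology metrics of a network
#'
#' Computes the clustering coefficient, characteristic path length, global
#' and local efficiency, and mean connectivity of a weighted network in
#' one call.
#'
#' @param network A `coherence_network` or symmetric weight matrix.
#' @return An object of class `topology_metrics`: list with scalars
#'   `clustering`, `path_length`, `global_eff`, `local_eff`,
#'   `mean_connectivity`, `n_edges`, and per-node vectors
#'   `clustering_by_node`, `local_eff_by_node`.
#' @export
topology_metrics <- function(network) {
  w <- net_weights(network)
  cc <- clustering_coefficient(w)
  le <- local_efficiency(w)
  eg <- global_efficiency(w)
  pl <- if (eg > 0) 1 / eg else NaN
  structure(list(
    clustering = cc$mean, path_length = pl, global_eff = eg,
    local_eff = le$mean, mean_connectivity = mean_connectivity(w),
    n_edges = sum(w[upper.tri(w)] > 0),
    clustering_by_node = cc$by_node, local_eff_by_node = le$by_node
  ), class = "topology_metrics")
}

#' @export
print.topology_metrics <- function(x, ...) {
  cat(sprintf(paste0("topology_metrics: C = %.4f, L = %.4f, E_glob = %.4f, ",
                     "E_loc = %.4f, mean connectivity = %.4f (%d edges)\n"),
              x$clustering, x$path_length, x$global_eff, x$local_eff,
              x$mean_connectivity, x$n_edges))
  invisible(x)
}
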