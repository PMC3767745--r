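## round-half-up, used for edge-count rounding (configurable via `rounding`
## arguments below); R's round() is round-half-even, which is not wanted here
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

#' Common sparsity value over a collection of networks
#'
#' Coherence is never exactly zero, so raw networks contain spurious weak
#' edges. The sparsity search scans a weight cutoff `t` from 0 to 1 in
#' steps of `step`; at each cutoff, edges with weight `< t` are deleted
#' from every network. Let `t*` be the first cutoff at which any network
#' contains an isolated node ("sole node"). The sparsity value is the
#' largest fraction of edges that any network still retains at the
#' preceding cutoff `t* - step`: thresholding each network to that common
#' edge fraction keeps all networks free of isolated nodes while removing
#' as many weak edges as possible. If no cutoff up to 1 isolates a node,
#' the sparsity is 1.
#'
#' @param networks List of `coherence_network` objects (or plain symmetric
#'   matrices) with the same node count.
#' @param step Cutoff increment (default 0.01).
#' @param rounding Rounding rule for the retained edge count,
#'   `"half-up"` (default) or `"half-even"`.
#' @return An object of class `sparsity_result`: list with `sparsity`,
#'   `critical_threshold` (the cutoff `t*`, `NA` if never reached),
#'   `n_edges_kept` and `n_possible`.
#' @export
find_sparsity <- function(networks, step = 0.01,
                          rounding = c("half-up", "half-even")) {
  rounding <- match.arg(rounding)
  if (!length(networks)) stop("at least one network is required")
  stopifnot(step > 0)
  mats <- lapply(networks, net_weights)
  n <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, integer(1)) != n)) stop("node count mismatch")
  m_possible <- n * (n - 1) / 2
  ## node i becomes isolated at the first cutoff t with t > max_j w_ij
  row_max <- vapply(mats, function(w) {
    diag(w) <- 0
    apply(w, 1, max)
  }, numeric(n))
  if (any(row_max <= 0)) {
    stop("a network already contains an isolated node at cutoff 0")
  }
  cuts <- (0:round(1 / step)) * step
  iso_at <- vapply(cuts, function(t) any(row_max < t - 1e-12), logical(1))
  if (!any(iso_at)) {
    return(structure(list(sparsity = 1, critical_threshold = NA_real_,
                          n_edges_kept = as.integer(m_possible),
                          n_possible = m_possible),
                     class = "sparsity_result"))
  }
  t_star <- cuts[which(iso_at)[1]]
  t_prev <- t_star - step
  frac <- vapply(mats, function(w) {
    wt <- w[upper.tri(w)]
    kept <- sum(wt > 0 & wt >= t_prev - 1e-12) # zero weight = no edge
    kept / m_possible
  }, numeric(1))
  sparsity <- max(frac)
  kept <- if (rounding == "half-up") round_half_up(sparsity * m_possible) else
    round(sparsity * m_possible)
  structure(list(sparsity = sparsity, critical_threshold = t_star,
                 n_edges_kept = as.integer(kept), n_possible = m_possible),
            class = "sparsity_result")
}

#' @export
print.sparsity_result <- function(x, ...) {
  cat(sprintf("sparsity_result: sparsity %.4f (%d of %d edges kept), critical cutoff %s\n",
              x$sparsity, x$n_edges_kept, x$n_possible,
              ifelse(is.na(x$critical_threshold), "none",
                     sprintf("%.2f", x$critical_threshold))))
  invisible(x)
}

#' Threshold a network to a given sparsity (Network 0)
#'
#' Keeps the `round(sparsity * N(N-1)/2)` largest-weight edges and sets all
#' other weights to zero; the node set is unchanged. Ties at the cut are
#' broken deterministically by weight (descending), then by the
#' lexicographic order of the node pair. The result for a subject's
#' original whole network is its "Network 0".
#'
#' @param network A `coherence_network` (or symmetric matrix).
#' @param sparsity Fraction of edges to keep, in `(0, 1]`; typically the
#'   value found by [find_sparsity()].
#' @param rounding Rounding rule for the edge count, `"half-up"` (default)
#'   or `"half-even"`.
#' @return A `coherence_network` with the same nodes and exactly the
#'   requested number of nonzero edges.
#' @export
apply_sparsity <- function(network, sparsity,
                           rounding = c("half-up", "half-even")) {
  rounding <- match.arg(rounding)
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  w <- net_weights(network)
  n <- nrow(w)
  m_possible <- n * (n - 1) / 2
  m <- if (rounding == "half-up") round_half_up(sparsity * m_possible) else
    round(sparsity * m_possible)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  if (m > sum(wt > 0)) {
    if (sparsity == 1) {
      m <- sum(wt > 0) # sparsity 1 is the identity: keep every edge
    } else {
      stop(sprintf("requested %d edges but only %d nonzero edges are available",
                   m, sum(wt > 0)))
    }
  }
  ord <- order(-wt, ut[, 1], ut[, 2])
  keep <- ord[seq_len(m)]
  out <- matrix(0, n, n)
  out[ut[keep, , drop = FALSE]] <- wt[keep]
  out <- out + t(out)
  labels <- if (inherits(network, "coherence_network")) network$labels else rownames(w)
  sf <- if (inherits(network, "coherence_network")) network$stim_freq else NA_real_
  ne <- if (inherits(network, "coherence_network")) network$n_epochs else 1L
  coherence_network(out, labels = labels, stim_freq = sf, n_epochs = ne)
}
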