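#' Edge-wise correlation between connection strength and SNR
#'
#' For every edge present in at least one subject's Network 0, the Pearson
#' correlation is computed across subjects between that edge's connection
#' strengths and the subjects' mean SNRs. Top-edge thresholding is applied
#' per subject, so edge sets may differ between subjects; a subject lacking
#' an edge contributes a weight of zero. Two-sided p-values come from the
#' t-distribution transform of r with `n - 2` degrees of freedom. An edge
#' whose weights (or the SNR vector) have zero variance has an undefined
#' correlation; it is flagged and later classified as non-significant.
#'
#' @param networks0 List of per-subject `coherence_network` objects
#'   (typically Network 0 from [apply_sparsity()]), sharing node labels.
#' @param snrs Numeric vector of per-subject mean SNRs, same length and
#'   order as `networks0` (at least 3 subjects).
#' @return An object of class `edge_correlation`: a data frame with
#'   columns `node_i`, `node_j`, `r`, `p`, `n`, `degenerate`, plus a
#'   `labels` attribute.
#' @export
edgewise_correlation <- function(networks0, snrs) {
  if (length(networks0) != length(snrs)) {
    stop("'networks0' and 'snrs' must have one entry per subject")
  }
  if (length(snrs) < 3) stop("at least 3 subjects are required")
  mats <- lapply(networks0, net_weights)
  labels <- if (inherits(networks0[[1]], "coherence_network")) {
    networks0[[1]]$labels
  } else {
    rownames(mats[[1]])
  }
  for (m in mats) {
    if (nrow(m) != nrow(mats[[1]])) stop("node count mismatch between subjects")
  }
  n_nodes <- nrow(mats[[1]])
  ut <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  W <- vapply(mats, function(m) m[upper.tri(m)], numeric(nrow(ut)))
  W <- matrix(W, nrow = nrow(ut))
  in_union <- rowSums(W != 0) > 0
  idx <- which(in_union)
  n <- length(snrs)
  snr_const <- stats::sd(snrs) == 0
  res <- lapply(idx, function(e) {
    wts <- W[e, ]
    if (snr_const || stats::sd(wts) == 0) {
      return(list(r = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    ct <- stats::cor.test(wts, snrs, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
  })
  out <- data.frame(
    node_i = labels[ut[idx, 1]],
    node_j = labels[ut[idx, 2]],
    r = vapply(res, `[[`, numeric(1), "r"),
    p = vapply(res, `[[`, numeric(1), "p"),
    n = n,
    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
    stringsAsFactors = FALSE
  )
  if (any(out$degenerate)) {
    warning(sum(out$degenerate),
            " edge(s) with zero variance: correlation undefined, classified non-significant")
  }
  structure(out, labels = labels, class = c("edge_correlation", "data.frame"))
}

#' Classify edges into the Network 1/2/3 partition
#'
#' Splits the edges of Network 0 into three classes by the sign and
#' significance of their across-subject correlation with SNR: `positive`
#' (Network 1: `p < alpha` and `r > 0`), `negative` (Network 3:
#' `p < alpha` and `r < 0`) and `nonsig` (Network 2: the remaining edges).
#' No multiple-testing correction is applied (`alpha` is an uncorrected
#' per-edge level). Classification is group-level: the same partition
#' applies to every subject, only the weights differ.
#'
#' @param corr An [edgewise_correlation()] result.
#' @param alpha Significance level in `(0, 1)`, default 0.05.
#' @return An object of class `network_partition`: list with `edges` (the
#'   correlation table plus a `class` column), `alpha` and `labels`.
#' @export
classify_edges <- function(corr, alpha = 0.05) {
  stopifnot(inherits(corr, "edge_correlation"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  cls <- rep("nonsig", nrow(corr))
  sig <- !is.na(corr$p) & corr$p < alpha
  cls[sig & corr$r > 0] <- "positive"
  cls[sig & corr$r < 0] <- "negative"
  edges <- cbind(as.data.frame(corr), class = cls, stringsAsFactors = FALSE)
  structure(list(edges = edges, alpha = alpha, labels = attr(corr, "labels")),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  tab <- table(factor(x$edges$class, c("positive", "nonsig", "negative")))
  cat(sprintf("network_partition (alpha = %g): %d positive, %d nonsig, %d negative edges\n",
              x$alpha, tab[["positive"]], tab[["nonsig"]], tab[["negative"]]))
  invisible(x)
}

#' Extract a class sub-network (Network 1, 2 or 3) for one subject
#'
#' Returns the subject's Network 0 restricted to the edges of the requested
#' class: `"positive"` gives Network 1, `"nonsig"` Network 2 and
#' `"negative"` Network 3. Node set is unchanged; isolated nodes are
#' permitted. The three class sub-networks partition Network 0's edges, so
#' their weight matrices sum to Network 0's weight matrix.
#'
#' @param network0 The subject's Network 0 (`coherence_network`).
#' @param partition A [classify_edges()] result.
#' @param cls One of `"positive"`, `"nonsig"`, `"negative"`.
#' @return A `coherence_network` holding only the requested class's edges.
#' @export
subnetwork <- function(network0, partition, cls = c("positive", "nonsig", "negative")) {
  cls <- match.arg(cls)
  stopifnot(inherits(partition, "network_partition"))
  w <- net_weights(network0)
  labels <- if (inherits(network0, "coherence_network")) network0$labels else
    rownames(w)
  if (!identical(labels, partition$labels)) stop("node label mismatch")
  keep <- matrix(FALSE, nrow(w), ncol(w))
  e <- partition$edges[partition$edges$class == cls, , drop = FALSE]
  if (nrow(e)) {
    i <- match(e$node_i, labels)
    j <- match(e$node_j, labels)
    keep[cbind(i, j)] <- TRUE
    keep[cbind(j, i)] <- TRUE
  }
  out <- w * keep
  sf <- if (inherits(network0, "coherence_network")) network0$stim_freq else NA_real_
  ne <- if (inherits(network0, "coherence_network")) network0$n_epochs else 1L
  coherence_network(out, labels = labels, stim_freq = sf, n_epochs = ne)
}
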