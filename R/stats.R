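#' Pearson correlation with two-sided significance
#'
#' Sample Pearson correlation with the usual two-sided p-value from the
#' t-distribution transform of r with `n - 2` degrees of freedom (via
#' [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return List with `r`, `p` and `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Pearson correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation table between network metrics and SNR across subjects
#'
#' One row per metric (`mean_connectivity`, `clustering`, `path_length`,
#' `global_eff`, `local_eff`): the Pearson correlation across subjects
#' between that metric of the given network and the subjects' mean SNRs.
#'
#' @param metrics List of [topology_metrics()] objects (or a data frame
#'   with the five metric columns), one per subject.
#' @param snrs Numeric vector of per-subject mean SNRs, aligned with
#'   `metrics`.
#' @param condition Condition label recorded in the table (e.g.
#'   `"12.5Hz"`).
#' @param network_id Which network the metrics describe (0, 1 or 2).
#' @return A data frame with columns `condition`, `network_id`,
#'   `metric`, `r`, `p`, `n`.
#' @export
metric_snr_correlations <- function(metrics, snrs, condition = NA_character_,
                                    network_id = NA_integer_) {
  metric_names <- c("mean_connectivity", "clustering", "path_length",
                    "global_eff", "local_eff")
  if (is.data.frame(metrics)) {
    tab <- metrics[, metric_names, drop = FALSE]
  } else {
    tab <- as.data.frame(lapply(metric_names, function(m)
      vapply(metrics, `[[`, numeric(1), m)))
    names(tab) <- metric_names
  }
  if (nrow(tab) != length(snrs)) stop("one metrics row per subject is required")
  rows <- lapply(metric_names, function(m) {
    x <- tab[[m]]
    if (anyNA(x) || !is.finite(stats::sd(x)) || stats::sd(x) == 0 ||
        stats::sd(snrs) == 0) {
      warning("metric '", m, "' is degenerate (constant or undefined); ",
              "correlation reported as NA")
      return(data.frame(condition = condition, network_id = network_id,
                        metric = m, r = NA_real_, p = NA_real_,
                        n = length(snrs), stringsAsFactors = FALSE))
    }
    pr <- pearson(x, snrs)
    data.frame(condition = condition, network_id = network_id, metric = m,
               r = pr$r, p = pr$p, n = pr$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Split subjects into high- and low-SNR groups
#'
#' Selects the `k` subjects with the highest mean SNR (Group 1) and the
#' `k` with the lowest (Group 2) for a two-group network comparison.
#'
#' @param networks List of per-subject networks.
#' @param snrs Per-subject mean SNRs aligned with `networks`.
#' @param k Group size (default 4).
#' @return List with `high`, `low` (network lists) and `high_idx`,
#'   `low_idx` (subject indices).
#' @export
split_groups_by_snr <- function(networks, snrs, k = 4) {
  stopifnot(length(networks) == length(snrs), 2 * k <= length(snrs))
  ord <- order(snrs, decreasing = TRUE)
  hi <- ord[seq_len(k)]
  lo <- rev(ord)[seq_len(k)]
  list(high = networks[hi], low = networks[lo], high_idx = hi, low_idx = lo)
}

#' Edge-wise two-group permutation test on connection weights
#'
#' For every edge, the observed statistic is the difference in mean weight
#' between Group 1 and Group 2. Under the null hypothesis that group
#' membership is exchangeable, subjects are randomly re-partitioned into
#' groups of the original sizes and the differences recomputed; the
#' one-tailed p-value is the proportion of permuted differences at least
#' as extreme as the observed one, in the direction of its sign. Sampled
#' p-values use the add-one estimator `(b + 1) / (n_perm + 1)`, which is
#' never exactly zero. When the number of distinct re-partitions is at
#' most `exact_limit` (70 splits for 4 + 4 subjects), all of them are
#' enumerated instead and the p-value is the exact proportion over the
#' splits (which include the observed labelling).
#'
#' @param networksA,networksB Lists of `coherence_network` objects (or
#'   matrices) for Group 1 and Group 2, sharing node labels.
#' @param n_perm Number of sampled permutations (default 5000).
#' @param seed Optional integer seed for the sampled mode.
#' @param method `"auto"` (exact when feasible, default), `"exact"` or
#'   `"sample"`.
#' @param exact_limit Maximum number of distinct splits for automatic
#'   exact enumeration (default 10000).
#' @return An object of class `permutation_result`: data frame with
#'   columns `node_i`, `node_j`, `diff`, `p`, plus attributes `method`,
#'   `n_perm` (permutations drawn or splits enumerated) and `seed`.
#' @export
group_permutation_test <- function(networksA, networksB, n_perm = 5000,
                                   seed = NULL,
                                   method = c("auto", "exact", "sample"),
                                   exact_limit = 10000) {
  method <- match.arg(method)
  nA <- length(networksA)
  nB <- length(networksB)
  if (nA < 1 || nB < 1) stop("both groups must be non-empty")
  mats <- lapply(c(networksA, networksB), net_weights)
  labels <- if (inherits(networksA[[1]], "coherence_network")) {
    networksA[[1]]$labels
  } else {
    rownames(mats[[1]])
  }
  n <- nA + nB
  ut <- which(upper.tri(mats[[1]]), arr.ind = TRUE)
  W <- vapply(mats, function(m) m[upper.tri(m)], numeric(nrow(ut)))
  W <- matrix(W, nrow = nrow(ut))
  obs <- rowMeans(W[, seq_len(nA), drop = FALSE]) -
    rowMeans(W[, nA + seq_len(nB), drop = FALSE])
  n_splits <- choose(n, nA)
  use_exact <- method == "exact" || (method == "auto" && n_splits <= exact_limit)
  if (use_exact) {
    splits <- utils::combn(n, nA)
    ind <- matrix(0, n, ncol(splits))
    ind[cbind(as.vector(splits), rep(seq_len(ncol(splits)), each = nA))] <- 1
    diffs <- W %*% (ind / nA - (1 - ind) / nB)
    pos <- obs >= 0
    p <- numeric(length(obs))
    p[pos] <- rowMeans(diffs[pos, , drop = FALSE] >= obs[pos] - 1e-12)
    p[!pos] <- rowMeans(diffs[!pos, , drop = FALSE] <= obs[!pos] + 1e-12)
    n_used <- ncol(splits)
    mode <- "exact"
  } else {
    draws <- with_preserved_rng({
      if (!is.null(seed)) set.seed(seed)
      replicate(n_perm, sample.int(n, nA))
    })
    ind <- matrix(0, n, n_perm)
    ind[cbind(as.vector(draws), rep(seq_len(n_perm), each = nA))] <- 1
    diffs <- W %*% (ind / nA - (1 - ind) / nB)
    pos <- obs >= 0
    b <- numeric(length(obs))
    b[pos] <- rowSums(diffs[pos, , drop = FALSE] >= obs[pos] - 1e-12)
    b[!pos] <- rowSums(diffs[!pos, , drop = FALSE] <= obs[!pos] + 1e-12)
    p <- (b + 1) / (n_perm + 1)
    n_used <- n_perm
    mode <- "sample"
  }
  out <- data.frame(node_i = labels[ut[, 1]], node_j = labels[ut[, 2]],
                    diff = obs, p = p, stringsAsFactors = FALSE)
  structure(out, method = mode, n_perm = n_used, seed = seed,
            class = c("permutation_result", "data.frame"))
}
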