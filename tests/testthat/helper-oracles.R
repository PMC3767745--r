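## Independent brute-force oracles. These deliberately share no code with
## the package: paths are enumerated explicitly, coherence is evaluated
## straight from its definition with bare stats::fft calls.

## random symmetric weight matrix in [0,1] with edge probability p
rand_graph <- function(n, p = 0.7) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- stats::runif(length(ut)) < p
  w[ut[on]] <- stats::runif(sum(on), 0.05, 1)
  w + t(w)
}

## guarantee every node has at least one edge (connected enough for E > 0)
rand_connected_graph <- function(n) {
  repeat {
    w <- rand_graph(n, 0.8)
    if (all(rowSums(w > 0) > 0)) return(w)
  }
}

## all simple paths between every pair, by explicit recursion over
## intermediate vertices; length of an edge is 1/weight
bf_shortest_paths <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  walk <- function(current, target, visited, acc) {
    if (acc >= best[walk_src, target]) {
      # still continue: acc only grows, so prune
      return(invisible(NULL))
    }
    if (current == target) {
      best[walk_src, target] <<- acc
      return(invisible(NULL))
    }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && is.finite(len[current, nxt])) {
        visited[nxt] <- TRUE
        walk(nxt, target, visited, acc + len[current, nxt])
        visited[nxt] <- FALSE
      }
    }
    invisible(NULL)
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      walk_src <- i
      visited <- rep(FALSE, n)
      visited[i] <- TRUE
      walk(i, j, visited, 0)
    }
  }
  best
}

bf_clustering <- function(w) {
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(w[i, ] > 0)
    k <- length(nbr)
    if (k < 2) next
    s <- 0
    for (j in nbr) for (h in nbr) {
      if (j != h && w[j, h] > 0) {
        s <- s + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    ci[i] <- s / (k * (k - 1))
  }
  list(by_node = ci, mean = mean(ci))
}

bf_global_eff <- function(w) {
  d <- bf_shortest_paths(w)
  n <- nrow(w)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_char_path <- function(w) 1 / bf_global_eff(w)

bf_local_eff <- function(w) {
  n <- nrow(w)
  el <- numeric(n)
  for (i in seq_len(n)) {
    nbr <- which(w[i, ] > 0)
    if (length(nbr) >= 2) el[i] <- bf_global_eff(w[nbr, nbr, drop = FALSE])
  }
  list(by_node = el, mean = mean(el))
}

## magnitude-squared coherence at the bin nearest f0, computed directly
## from the definition with explicit loops over sub-windows and pairs
bf_coherence <- function(epoch, fs, f0, subwindow_s = 1.2, sub_overlap = 0.5,
                         taper = "hann") {
  nsub <- round(subwindow_s * fs)
  step <- round(nsub * (1 - sub_overlap))
  starts <- seq(0, ncol(epoch) - nsub, by = step)
  win <- if (taper == "hann") {
    0.5 * (1 - cos(2 * pi * (0:(nsub - 1)) / nsub))
  } else {
    rep(1, nsub)
  }
  freqs <- (0:(nsub - 1)) * fs / nsub
  half <- freqs <= fs / 2 + 1e-9
  bin <- which(half)[which.min(abs(freqs[half] - f0))]
  C <- nrow(epoch)
  Z <- array(0i, c(length(starts), C))
  for (k in seq_along(starts)) {
    for (c in seq_len(C)) {
      seg <- epoch[c, (starts[k] + 1):(starts[k] + nsub)] * win
      Z[k, c] <- stats::fft(seg)[bin]
    }
  }
  coh <- matrix(0, C, C)
  for (a in seq_len(C)) for (b in seq_len(C)) {
    if (a == b) next
    sxy <- mean(Z[, a] * Conj(Z[, b]))
    sxx <- mean(Mod(Z[, a])^2)
    syy <- mean(Mod(Z[, b])^2)
    coh[a, b] <- Mod(sxy)^2 / (sxx * syy)
  }
  coh
}

## brute-force epoch start-time enumeration
bf_epoch_starts <- function(n_samples, nwin, nstep) {
  starts <- integer(0)
  s <- 0
  while (s + nwin <= n_samples) {
    starts <- c(starts, s)
    s <- s + nstep
  }
  starts
}

## small sinusoidal test epoch with per-channel noise
toy_epoch <- function(n_channels, fs = 250, dur = 2.4, f0 = 12.5,
                      noise = 0.5) {
  tt <- (0:(dur * fs - 1)) / fs
  t(vapply(seq_len(n_channels), function(c) {
    sin(2 * pi * f0 * tt + c) + stats::rnorm(length(tt), 0, noise)
  }, numeric(length(tt))))
}
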