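#' Construct a coherence network object
#'
#' A symmetric, nonnegative weighted adjacency matrix over the electrode
#' montage, with weights in `[0, 1]` and a zero diagonal (self-loops are
#' excluded from all network measures).
#'
#' @param weights Square symmetric numeric matrix of edge weights in
#'   `[0, 1]`.
#' @param labels Node labels; defaults to the row names of `weights` or
#'   `"ch1"`, `"ch2"`, ...
#' @param stim_freq Frequency (Hz) at which the coherence was evaluated.
#' @param n_epochs Number of epochs averaged into the weights.
#' @return An object of class `coherence_network`.
#' @export
coherence_network <- function(weights, labels = NULL, stim_freq = NA_real_,
                              n_epochs = 1L) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-8) stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (min(weights) < -1e-9 || max(weights) > 1 + 1e-9) {
    stop("weights must lie in [0, 1]")
  }
  weights <- pmin(pmax(weights, 0), 1)
  diag(weights) <- 0
  if (is.null(labels)) labels <- rownames(weights)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, stim_freq = stim_freq,
                 n_epochs = as.integer(n_epochs)),
            class = "coherence_network")
}

#' @export
as.matrix.coherence_network <- function(x, ...) x$weights

#' @export
print.coherence_network <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("coherence_network: %d nodes, %d nonzero edges (of %d), frequency %.4g Hz, %d epoch(s)\n",
              length(x$labels), sum(w > 0), length(w), x$stim_freq, x$n_epochs))
  cat(sprintf("  weights: min %.3f, median %.3f, max %.3f\n",
              min(w), stats::median(w), max(w)))
  invisible(x)
}

net_weights <- function(x) {
  if (inherits(x, "coherence_network")) x$weights else as.matrix(x)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Narrow-band coherence matrix of one epoch
#'
#' Magnitude-squared coherence between every channel pair at the FFT bin
#' nearest the stimulus frequency,
#' `|mean_k C_xy,k|^2 / (mean_k C_xx,k * mean_k C_yy,k)`, where the
#' cross- and auto-spectra are averaged over Welch sub-windows `k` of the
#' epoch. A single window would make the estimate identically 1, so at
#' least two sub-windows are required; the default 1.2 s sub-window with
#' 50% overlap gives three sub-windows per 2.4 s epoch while still holding
#' an integer number of cycles of both 12.5 Hz and 16.67 Hz.
#'
#' @param epoch Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in samples/s.
#' @param stim_freq Stimulus frequency in Hz.
#' @param subwindow_s Sub-window length in seconds.
#' @param sub_overlap Fractional overlap between consecutive sub-windows in
#'   `[0, 1)`.
#' @param taper Sub-window taper, `"hann"` (default) or `"rect"`.
#' @return A `coherence_network` with `n_epochs = 1`.
#' @export
epoch_coherence <- function(epoch, fs, stim_freq, subwindow_s = 1.2,
                            sub_overlap = 0.5, taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  epoch <- as.matrix(epoch)
  nsub <- subwindow_s * fs
  if (abs(nsub - round(nsub)) > 1e-8) stop("subwindow_s * fs must be an integer")
  nsub <- as.integer(round(nsub))
  if (ncol(epoch) < nsub) stop("epoch is shorter than one sub-window")
  if (sub_overlap < 0 || sub_overlap >= 1) stop("sub_overlap must be in [0, 1)")
  nstep <- max(1L, as.integer(round(nsub * (1 - sub_overlap))))
  starts <- seq.int(0L, ncol(epoch) - nsub, by = nstep)
  K <- length(starts)
  if (K < 2) stop("need at least two sub-windows (coherence from one is identically 1)")
  w <- if (taper == "hann") hann_window(nsub) else rep(1, nsub)
  freq <- (seq_len(nsub) - 1) * fs / nsub
  pos <- which(freq <= fs / 2 + 1e-9)
  bin0 <- pos[which.min(abs(freq[pos] - stim_freq))]
  ## K x C matrix of complex FFT coefficients at the stimulus bin
  Z <- t(vapply(starts, function(s) {
    seg <- epoch[, (s + 1):(s + nsub), drop = FALSE]
    stats::mvfft(t(seg) * w)[bin0, ]
  }, complex(nrow(epoch))))
  Z <- matrix(Z, nrow = K)
  S <- (t(Conj(Z)) %*% Z) / K # C x C cross-spectral matrix at the bin
  auto <- Re(diag(S))
  if (any(auto <= 0)) {
    bad <- rownames(epoch)[auto <= 0]
    if (is.null(bad)) bad <- which(auto <= 0)
    stop("coherence undefined: zero auto-spectrum at the stimulus bin for channel(s) ",
         paste(bad, collapse = ", "))
  }
  coh <- Mod(S)^2 / outer(auto, auto)
  coh <- pmin(coh, 1) # guard tiny floating-point overshoot of the bound
  diag(coh) <- 0
  coherence_network(coh, labels = rownames(epoch), stim_freq = freq[bin0],
                    n_epochs = 1L)
}

#' Average a list of coherence networks element-wise
#'
#' @param networks List of `coherence_network` objects sharing node labels
#'   and stimulus frequency.
#' @return A `coherence_network` whose weights are the arithmetic mean of
#'   the inputs and whose `n_epochs` is the total epoch count.
#' @export
average_networks <- function(networks) {
  if (!length(networks)) stop("empty network list")
  stopifnot(all(vapply(networks, inherits, logical(1), "coherence_network")))
  ref <- networks[[1]]
  for (nw in networks[-1]) {
    if (!identical(nw$labels, ref$labels)) stop("node label mismatch")
    if (!isTRUE(all.equal(nw$stim_freq, ref$stim_freq))) {
      stop("stimulus frequency mismatch")
    }
  }
  avg <- Reduce(`+`, lapply(networks, `[[`, "weights")) / length(networks)
  coherence_network(avg, labels = ref$labels, stim_freq = ref$stim_freq,
                    n_epochs = sum(vapply(networks, `[[`, integer(1), "n_epochs")))
}

#' Averaged coherence network of a recording
#'
#' Extracts epochs from all segments, computes the per-epoch narrow-band
#' coherence matrices and averages them into the subject's original whole
#' network (9-12 segments of 6 s give 36-48 per-epoch matrices).
#'
#' @param recording A `recording` object.
#' @param stim_freq Stimulus frequency in Hz; defaults to the frequency
#'   stored in the recording.
#' @inheritParams extract_epochs
#' @inheritParams epoch_coherence
#' @return A `coherence_network` averaged over all epochs.
#' @export
recording_network <- function(recording, stim_freq = recording$stim_freq,
                              window_s = 2.4, overlap_s = 1.2,
                              subwindow_s = 1.2, sub_overlap = 0.5) {
  es <- recording_epochs(recording, window_s, overlap_s)
  mats <- lapply(es$epochs, epoch_coherence, fs = es$fs, stim_freq = stim_freq,
                 subwindow_s = subwindow_s, sub_overlap = sub_overlap)
  average_networks(mats)
}
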