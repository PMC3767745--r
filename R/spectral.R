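#' Extract overlapping epochs from a segment
#'
#' Cuts a channels-by-samples segment into fixed-length epochs whose start
#' times advance by `window_s - overlap_s` seconds. Only fully contained
#' windows are emitted, so a segment of duration `T` yields
#' `floor((T - window_s) / (window_s - overlap_s)) + 1` epochs. The default
#' 2.4 s window holds an integer number of cycles of both 12.5 Hz and
#' 16.67 Hz, which places those stimulus frequencies exactly on FFT bins.
#'
#' @param segment Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in samples/s.
#' @param window_s Epoch length in seconds; `window_s * fs` must be an
#'   integer.
#' @param overlap_s Overlap between consecutive epochs in seconds,
#'   `0 <= overlap_s < window_s`.
#' @return An object of class `epoch_set`: list with `epochs` (list of
#'   channel-by-sample matrices), `window_s`, `overlap_s`, `fs`.
#' @export
extract_epochs <- function(segment, fs, window_s = 2.4, overlap_s = 1.2) {
  segment <- as.matrix(segment)
  stopifnot(fs > 0, window_s > 0)
  if (overlap_s < 0 || overlap_s >= window_s) {
    stop("'overlap_s' must satisfy 0 <= overlap_s < window_s")
  }
  nwin <- window_s * fs
  if (abs(nwin - round(nwin)) > 1e-8) stop("window_s * fs must be an integer")
  nwin <- as.integer(round(nwin))
  nstep <- as.integer(round((window_s - overlap_s) * fs))
  if (nstep < 1) stop("epoch step must be at least one sample")
  nsamp <- ncol(segment)
  if (nsamp < nwin) {
    stop(sprintf("segment (%d samples) is shorter than one %g s window",
                 nsamp, window_s))
  }
  starts <- seq.int(0L, nsamp - nwin, by = nstep)
  epochs <- lapply(starts, function(s) segment[, (s + 1):(s + nwin), drop = FALSE])
  structure(list(epochs = epochs, window_s = window_s, overlap_s = overlap_s,
                 fs = fs),
            class = "epoch_set")
}

#' Extract epochs from every segment of a recording
#'
#' @param recording A `recording` object (see [generate_subject()] or
#'   [read_recording()]).
#' @inheritParams extract_epochs
#' @return An `epoch_set` pooling the epochs of all segments, in segment
#'   order.
#' @export
recording_epochs <- function(recording, window_s = 2.4, overlap_s = 1.2) {
  sets <- lapply(recording$segments, extract_epochs, fs = recording$fs,
                 window_s = window_s, overlap_s = overlap_s)
  structure(list(epochs = unlist(lapply(sets, `[[`, "epochs"), recursive = FALSE),
                 window_s = window_s, overlap_s = overlap_s, fs = recording$fs),
            class = "epoch_set")
}

#' Per-channel power spectrum of an epoch
#'
#' Squared FFT magnitude scaled so that Parseval's identity holds: the sum
#' of power over all bins equals the mean square of the signal. No taper or
#' detrending is applied; with integer-cycle windows a stimulus-locked
#' sinusoid concentrates all its power in a single bin.
#'
#' @param epoch Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in samples/s.
#' @return A list with `power` (bins-by-channels matrix over all FFT bins)
#'   and `freq` (bin frequencies in Hz, `0` to `fs * (N - 1) / N`), with
#'   bin spacing `1 / window duration`.
#' @export
power_spectrum <- function(epoch, fs) {
  epoch <- as.matrix(epoch)
  if (ncol(epoch) < 1) stop("empty epoch")
  n <- ncol(epoch)
  X <- stats::mvfft(t(epoch))
  power <- Mod(X)^2 / n^2
  colnames(power) <- rownames(epoch)
  list(power = power, freq = (seq_len(n) - 1) * fs / n, fs = fs)
}

#' Stimulus-band signal-to-noise ratio
#'
#' Per channel, the SNR is the power at the FFT bin nearest the stimulus
#' frequency divided by the mean power over the bins of the
#' `band_hz`-wide band centred on that frequency, excluding the stimulus
#' bin itself; power spectra are first averaged across epochs, so the
#' ratio is taken on the epoch-averaged spectrum. (Averaging the
#' per-epoch ratios instead is statistically ill-behaved with a two-bin
#' noise band: the per-epoch denominator is a two-sample exponential
#' mean, whose reciprocal has infinite variance.) `mean_snr` averages the
#' channels. A zero noise-band power yields `Inf`, which is reported as
#' such rather than clipped.
#'
#' With 2.4 s epochs the bin spacing is 1/2.4 Hz, so the default 1 Hz band
#' comprises the two bins adjacent to the stimulus bin.
#'
#' @param spectra List of [power_spectrum()] results, one per epoch (all
#'   with the same bin grid).
#' @param stim_freq Stimulus frequency in Hz; must lie within the spectral
#'   range with at least one other bin inside the band.
#' @param band_hz Width of the noise band in Hz (default 1).
#' @return An object of class `snr_record`: list with `per_channel_snr`,
#'   `mean_snr`, `stim_freq`, `n_epochs`.
#' @export
compute_snr <- function(spectra, stim_freq, band_hz = 1) {
  if (!length(spectra)) stop("no spectra supplied")
  freq <- spectra[[1]]$freq
  fs <- spectra[[1]]$fs
  pos <- which(freq <= fs / 2 + 1e-9)
  if (stim_freq <= 0 || stim_freq > fs / 2) {
    stop("stimulus frequency outside the spectral range")
  }
  bin0 <- pos[which.min(abs(freq[pos] - stim_freq))]
  nb <- pos[abs(freq[pos] - stim_freq) <= band_hz / 2 + 1e-9]
  nb <- setdiff(nb, bin0)
  if (!length(nb)) {
    stop("no noise-band bin within ", band_hz / 2, " Hz of the stimulus bin")
  }
  avg <- Reduce(`+`, lapply(spectra, `[[`, "power")) / length(spectra)
  noise <- colMeans(avg[nb, , drop = FALSE])
  per_channel <- avg[bin0, ] / noise
  names(per_channel) <- colnames(spectra[[1]]$power)
  structure(list(per_channel_snr = per_channel,
                 mean_snr = mean(per_channel),
                 stim_freq = freq[bin0], n_epochs = length(spectra)),
            class = "snr_record")
}

#' SNR of a whole recording
#'
#' Convenience wrapper: extracts epochs from all segments, computes the
#' per-epoch power spectra and returns the epoch-averaged [compute_snr()]
#' record.
#'
#' @param recording A `recording` object.
#' @param stim_freq Stimulus frequency in Hz; defaults to the frequency
#'   stored in the recording.
#' @inheritParams extract_epochs
#' @inheritParams compute_snr
#' @return An `snr_record`.
#' @export
recording_snr <- function(recording, stim_freq = recording$stim_freq,
                          window_s = 2.4, overlap_s = 1.2, band_hz = 1) {
  es <- recording_epochs(recording, window_s, overlap_s)
  spectra <- lapply(es$epochs, power_spectrum, fs = es$fs)
  compute_snr(spectra, stim_freq, band_hz)
}

#' @export
print.snr_record <- function(x, ...) {
  cat(sprintf("snr_record: mean SNR %.3f over %d channels, %d epochs (stimulus bin %.4g Hz)\n",
              x$mean_snr, length(x$per_channel_snr), x$n_epochs, x$stim_freq))
  invisible(x)
}
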