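test_that("epoch extraction matches brute-force start enumeration", {
  set.seed(1)
  fs <- 250
  cases <- expand.grid(T = c(2.4, 3.6, 4.8, 6, 7.2, 9.6, 12, 14.4, 24, 30),
                       win = c(1.2, 2.4, 4.8), ovl_frac = c(0, 0.25, 0.5, 0.75))
  cases <- cases[cases$T >= cases$win, ]
  for (i in seq_len(nrow(cases))) {
    T <- cases$T[i]; win <- cases$win[i]
    ovl <- cases$ovl_frac[i] * win
    seg <- matrix(rnorm(2 * T * fs), 2)
    es <- extract_epochs(seg, fs, win, ovl)
    starts <- bf_epoch_starts(ncol(seg), round(win * fs), round((win - ovl) * fs))
    expect_length(es$epochs, length(starts))
    expect_length(es$epochs, floor((T - win) / (win - ovl) + 1e-9) + 1)
    ## first and last epoch contents line up with the enumerated starts
    last <- length(starts)
    expect_identical(es$epochs[[last]],
                     seg[, (starts[last] + 1):(starts[last] + round(win * fs)),
                         drop = FALSE])
  }
})

test_that("the protocol segmentation yields four epochs at 1.2 s spacing", {
  seg <- matrix(seq_len(2 * 1500), 2)
  es <- extract_epochs(seg, 250, 2.4, 1.2)
  expect_length(es$epochs, 4)
  expect_identical(es$epochs[[2]], seg[, 301:900])
  expect_length(extract_epochs(seg[, 1:600], 250, 2.4, 1.2)$epochs, 1)
  expect_error(extract_epochs(seg[, 1:500], 250, 2.4, 1.2), "shorter")
  expect_error(extract_epochs(seg, 250, 2.4, 2.4), "overlap_s")
})

test_that("power spectra satisfy Parseval and concentrate exact-bin sinusoids", {
  set.seed(2)
  epoch <- matrix(rnorm(3 * 600), 3)
  ps <- power_spectrum(epoch, 250)
  expect_equal(colSums(ps$power), rowMeans(epoch^2), tolerance = 1e-10)
  expect_equal(ps$freq[2] - ps$freq[1], 1 / 2.4, tolerance = 1e-12)
  ## 12.5 Hz is exactly 30 cycles in 2.4 s: a single positive-frequency bin
  tt <- (0:599) / 250
  ps2 <- power_spectrum(rbind(sin(2 * pi * 12.5 * tt)), 250)
  expect_equal(ps2$freq[31], 12.5)
  expect_equal(ps2$power[31, 1], 0.25, tolerance = 1e-10) # half of A^2/2
  other <- ps2$power[-c(31, 600 - 29), 1]
  expect_lt(max(other), 1e-20)
})

test_that("SNR is exactly one for flat spectra and invariant to rescaling", {
  ## an impulse has a perfectly flat magnitude spectrum
  epoch <- matrix(0, 2, 600)
  epoch[, 1] <- c(1, 2)
  sp <- list(power_spectrum(epoch, 250))
  rec <- compute_snr(sp, 12.5)
  expect_identical(unname(rec$per_channel_snr), c(1, 1))
  expect_identical(rec$mean_snr, 1)
  set.seed(3)
  noisy <- matrix(rnorm(2 * 600), 2) + toy_epoch(2, noise = 0)
  a <- compute_snr(list(power_spectrum(noisy, 250)), 12.5)
  b <- compute_snr(list(power_spectrum(noisy * 7.3, 250)), 12.5)
  expect_equal(a$per_channel_snr, b$per_channel_snr, tolerance = 1e-12)
})

test_that("SNR matches an independent FFT computation on sinusoid plus noise", {
  set.seed(4)
  fs <- 250
  for (rep in 1:40) {
    f0 <- sample(c(12.5, 1000 / 60), 1)
    segs <- replicate(3, toy_epoch(2, fs = fs, f0 = f0, noise = 1),
                      simplify = FALSE)
    spectra <- lapply(segs, power_spectrum, fs = fs)
    got <- compute_snr(spectra, f0)
    ## oracle: bare fft, Parseval scaling, epoch-averaged spectrum, 2-bin band
    pw <- sapply(segs, function(s) {
      apply(s, 1, function(ch) Mod(stats::fft(ch))^2 / length(ch)^2)
    })
    avg <- matrix(rowMeans(pw), ncol = 2)
    freqs <- (0:599) * fs / 600
    bin <- which.min(abs(freqs[1:301] - f0))
    nb <- setdiff(which(abs(freqs[1:301] - f0) <= 0.5 + 1e-9), bin)
    want <- avg[bin, ] / colMeans(avg[nb, , drop = FALSE])
    expect_equal(unname(got$per_channel_snr), unname(want), tolerance = 1e-10)
  }
})

test_that("pure-noise SNR has the inverse-Gamma corrected null mean", {
  set.seed(5)
  n_rep <- 400
  m_epochs <- 4
  snrs <- replicate(n_rep, {
    spectra <- replicate(m_epochs,
                         power_spectrum(matrix(rnorm(600), 1), 250),
                         simplify = FALSE)
    compute_snr(spectra, 12.5)$mean_snr
  })
  ## ratio of epoch-averaged bin powers: E = 2M / (2M - 1) for a 2-bin band
  expect_lt(abs(mean(snrs) - 2 * m_epochs / (2 * m_epochs - 1)),
            3 * sd(snrs) / sqrt(n_rep))
})

test_that("zero noise-band power reports an infinite SNR", {
  ## hand-built spectrum: all power at the stimulus bin, none in the band
  power <- matrix(0, 600, 1)
  power[31, 1] <- 1
  sp <- list(power = power, freq = (0:599) * 250 / 600, fs = 250)
  rec <- compute_snr(list(sp), 12.5)
  expect_identical(unname(rec$per_channel_snr), Inf)
  expect_identical(rec$mean_snr, Inf)
})
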