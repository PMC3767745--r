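small_config <- function(...) {
  generator_config(n_subjects = 3, n_channels = 6, n_segments = 2,
                   entrain_factors = c(0.6, 1, 1.8),
                   pos_edges = rbind(c(1, 4)), neg_edges = rbind(c(2, 5)),
                   ...)
}

test_that("configuration invariants are enforced", {
  expect_error(generator_config(segment_s = 6.001), "integer number of samples")
  expect_error(generator_config(entrain_factors = c(rep(1, 10), -1)),
               "positive")
  expect_error(generator_config(n_channels = 1), "n_channels")
  expect_error(
    generator_config(pos_edges = rbind(c("Fp1", "O1")),
                     neg_edges = rbind(c("O1", "Fp1"))),
    "disjoint")
  expect_error(generator_config(pos_edges = rbind(c("Fp1", "Nope"))),
               "unknown channel")
  ## two maximally pooled negative edges meeting at one channel overflow
  ## that channel's phase-noise variance budget
  expect_error(
    generator_config(n_channels = 6, n_subjects = 2,
                     entrain_factors = c(0.5, 1), pos_edges = NULL,
                     neg_edges = rbind(c(1, 2), c(2, 3))),
    "variance budget")
})

test_that("identical seeds give bit-identical cohorts and leave the RNG alone", {
  cfg <- small_config(seed = 11)
  set.seed(999)
  before <- .Random.seed
  a <- generate_cohort(cfg)
  expect_identical(.Random.seed, before)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  ## a different seed changes the data
  c <- generate_cohort(small_config(seed = 12))
  expect_false(identical(a$recordings[[1]]$segments[[1]],
                         c$recordings[[1]]$segments[[1]]))
  ## generate_subject reproduces the cohort member
  expect_identical(a$recordings[[2]], generate_subject(cfg, 2))
  expect_error(generate_subject(cfg, 4), "subject_index")
})

test_that("default cohort has the protocol dimensions", {
  cfg <- generator_config()
  expect_identical(cfg$channels, ssvep_montage())
  rec <- generate_subject(cfg, 6)
  expect_length(rec$segments, 12)
  expect_identical(dim(rec$segments[[1]]), c(18L, 1500L))
  expect_identical(rownames(rec$segments[[1]]), ssvep_montage())
  expect_identical(cfg$n_subjects, 11L)
})

test_that("ground truth covers every unordered pair with the planted classes", {
  cfg <- generator_config()
  truth <- generate_cohort(generator_config(n_subjects = 2,
                                            entrain_factors = c(1, 1.5),
                                            n_segments = 1))$truth
  expect_identical(nrow(truth$edge_class), 153L)
  tab <- table(truth$edge_class$class)
  expect_identical(as.integer(tab[["positive"]]), nrow(ssvepnet:::default_pos_edges()))
  expect_identical(as.integer(tab[["negative"]]), nrow(ssvepnet:::default_neg_edges()))
})

test_that("noiseless undrifting channels are pure sinusoids with unit coherence", {
  cfg <- generator_config(n_subjects = 1, n_channels = 2, n_segments = 1,
                          entrain_factors = 1, pos_edges = NULL,
                          neg_edges = NULL, noise_sd = 0, phase_jitter = 0,
                          topo_sd = 0, jitter_het = 0, bg_pools = 0,
                          harmonic_amp = 0)
  rec <- generate_subject(cfg, 1)
  x <- rec$segments[[1]]
  tt <- (0:1499) / 250
  ## pure sinusoid: matches a fitted cosine exactly
  fit <- function(ch) {
    ph <- atan2(-sum(ch * sin(2 * pi * 12.5 * tt)),
                sum(ch * cos(2 * pi * 12.5 * tt)))
    cos(2 * pi * 12.5 * tt + ph)
  }
  expect_equal(x[1, ], fit(x[1, ]), tolerance = 1e-8)
  ep <- extract_epochs(x, 250)$epochs[[1]]
  expect_equal(epoch_coherence(ep, 250, 12.5)$weights[1, 2], 1,
               tolerance = 1e-9)
  ## with coupling and no noise the channels remain deterministic and
  ## perfectly coherent at the stimulus bin
  cfg2 <- generator_config(n_subjects = 1, n_channels = 2, n_segments = 1,
                           entrain_factors = 1, pos_edges = rbind(c(1, 2)),
                           neg_edges = NULL, noise_sd = 0, phase_jitter = 0,
                           topo_sd = 0, jitter_het = 0, bg_pools = 0,
                           harmonic_amp = 0)
  ep2 <- extract_epochs(generate_subject(cfg2, 1)$segments[[1]], 250)$epochs[[1]]
  expect_equal(epoch_coherence(ep2, 250, 12.5)$weights[1, 2], 1,
               tolerance = 1e-9)
})

test_that("mean SNR increases strictly with the entrainment factor", {
  ## amplitude-driven regime: no drift, so the stimulus line is a pure
  ## tone and SNR grows as g^2 over the noise floor
  cfg <- generator_config(n_subjects = 5, n_segments = 4,
                          entrain_factors = seq(0.5, 2, length.out = 5),
                          noise_sd = 0.1, phase_jitter = 0, topo_sd = 0,
                          jitter_het = 0, bg_pools = 0, seed = 5)
  snr <- vapply(generate_cohort(cfg)$recordings,
                function(r) recording_snr(r)$mean_snr, numeric(1))
  expect_identical(order(snr), order(cfg$entrain_factors))
  expect_equal(cor(snr, cfg$entrain_factors, method = "spearman"), 1)
})
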