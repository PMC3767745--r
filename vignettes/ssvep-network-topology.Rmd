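---
title: "Coherence-network topology of steady-state visual responses: methods"
author: "ssvepnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence-network topology of steady-state visual responses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A visual stimulus flickering at a fixed rate above roughly 4 Hz entrains a
near-sinusoidal cortical response — the steady-state visual evoked
potential (SSVEP) — at the stimulus fundamental and its harmonics. The
strength of that response varies considerably between individuals viewing
the same stimulus. `ssvepnet` implements a network-level account of this
variability: it builds a weighted functional connectivity network from
multichannel recordings by measuring narrow-band coherence between
electrode pairs at the stimulus frequency, relates the network's weighted
graph topology to the response strength across subjects, and partitions
the network into sub-networks whose connection strengths are positively,
negatively or non-significantly related to the response.

The pipeline operates on cohorts shaped like a typical steady-state
protocol: around eleven subjects, two flicker frequencies whose cycle
durations (80 ms and 60 ms) give fundamentals of 12.5 Hz and 16.67 Hz, 18
widely spaced 10–20 electrodes, and 9–12 artifact-free 6 s segments per
subject and condition sampled at 250 Hz. Wide electrode spacing matters
because scalp coherence between close electrodes is dominated by volume
conduction rather than neural coupling.

## Pipeline stages

1. **Epochs.** Each 6 s segment is cut into 2.4 s epochs overlapping by
   1.2 s, so a segment yields 4 epochs and a subject contributes 36–48
   epochs. The 2.4 s length holds an integer number of cycles of both
   12.5 Hz (30 cycles) and 16.67 Hz (40 cycles), so both stimulus
   frequencies fall exactly on FFT bins and a stimulus-locked sinusoid
   suffers no spectral leakage with a plain rectangular window.
2. **SNR.** The response strength is the power at the stimulus bin of the
   epoch-averaged power spectrum divided by the mean power in the 1 Hz
   band centred on the stimulus frequency, excluding the stimulus bin
   itself. At 2.4 s resolution (bin spacing 1/2.4 Hz) that band contains
   exactly the two adjacent bins. Per-channel SNRs are averaged over the
   18 electrodes into one response measure per subject and condition.
3. **Coherence.** For every epoch, the magnitude-squared coherence
   `|mean_k C_xy,k|² / (mean_k C_xx,k · mean_k C_yy,k)` is evaluated at
   the single bin nearest the stimulus frequency, with the cross- and
   auto-spectra averaged over Welch sub-windows `k` (1.2 s Hann windows,
   50% overlap: three per epoch). A single window would make the estimate
   identically 1, which is why sub-averaging is required. The per-epoch
   18×18 matrices are averaged into the subject's *original whole
   network*.
4. **Sparsity and Network 0.** Coherence is never exactly zero, so the
   raw networks carry spurious weak edges. A cutoff is scanned from 0 to
   1 in steps of 0.01 over all subjects' original networks (both
   conditions pooled); the first cutoff at which any network acquires an
   isolated node stops the scan, and the sparsity value is the largest
   edge fraction any network retains at the preceding cutoff. Each
   network is then thresholded to its top `round(sparsity × 153)` edges —
   "Network 0" — so all subjects share an edge count while no network
   loses a node.
5. **Partition.** For every edge present in any subject's Network 0, the
   Pearson correlation between its connection strengths and the subjects'
   mean SNRs is computed across subjects (a subject lacking the edge
   contributes weight zero). Edges with `p < 0.05` (uncorrected,
   two-sided t transform) and `r > 0` form Network 1, significant
   negative edges form Network 3, and the remainder Network 2. The
   partition is group-level: the same edge classes apply to every
   subject, only the weights differ. Network 3 is typically very sparse
   and its graph metrics are not computed.
6. **Topology metrics.** Weighted clustering coefficient, harmonic-mean
   characteristic path length, global efficiency and local efficiency
   (below), plus the mean nonzero connection strength, are computed per
   subject for Networks 0, 1 and 2 and correlated with the mean SNRs.
7. **Group comparison.** The four highest-SNR and four lowest-SNR
   subjects are compared edge-wise by the difference in mean Network-0
   weight, with a one-tailed permutation test over random re-partitions
   of the eight subjects. With 4 + 4 subjects there are only 70 distinct
   splits, so the implementation enumerates them exactly whenever the
   split count is at most 10,000 and falls back to 5000 sampled
   permutations (with the add-one `(b + 1)/(n + 1)` estimator, which can
   never return zero) otherwise.

## Graph metrics

All metrics treat the coherence `w_ij ∈ [0, 1]` as the connection weight
and the inverse weight `1 / w_ij` as the edge length; absent edges have
infinite length. With `k_i` the number of nonzero-weight neighbours:

* **Clustering** (Onnela form):
  `C_i = Σ_{j,h} (w_ij w_ih w_jh)^{1/3} / (k_i (k_i − 1))`, zero when
  `k_i < 2`; the network value averages all N nodes. Coherence already
  lives on a natural `[0, 1]` scale, so weights enter as-is. Rescaling by
  the per-network maximum (available via `normalize = "max"`) would make
  the coefficient a purely relative measure of weight heterogeneity and
  discard the overall connectivity level — under a global rise of all
  coherences it can even *decrease* — which is not the quantity this
  analysis relates to response strength.
* **Characteristic path length** is the harmonic mean of all-pairs
  shortest path lengths, `L = N(N−1) / Σ_{i≠j} 1/L_ij` with `1/∞ = 0`:
  disconnected pairs drop out of the sum instead of making `L` infinite,
  so the measure stays defined on fragmented sub-networks.
* **Global efficiency** is the mean inverse shortest path length; by
  construction `E_glob · L = 1` exactly, and the test suite asserts this
  identity to machine precision on random graphs.
* **Local efficiency** of node *i* is the global efficiency of the
  subgraph induced by *i*'s direct neighbours (original weights, paths
  confined to the subgraph, node *i* excluded), zero for `k_i < 2`.

Shortest paths are computed by Floyd–Warshall over the 18-node montage;
only path lengths are reported, so ties need no tie-break. All four
metrics are validated against brute-force oracles (explicit path
enumeration, explicit triple sums) on 500 random graphs of up to six
nodes at a 10⁻⁹ tolerance.

## The synthetic cohort generator

No public recordings accompany this protocol, so the package ships a
generator that reproduces the statistical structure the analysis assumes,
with known ground truth. Each channel carries a stimulus-locked
oscillator `g · a_c · cos(2π f₀ t + φ_c + θ_c(t))` plus a second harmonic
and white noise, where `g` is the subject's entrainment factor,
`a_c` a subject-specific lognormal response topography, and `θ_c` a
random-walk phase drift.

Three design choices deserve explanation:

* **Entrainment tightens phase locking.** The drift rate is
  `phase_jitter · g^(−1/2)`: stronger drive concentrates the oscillation
  into a narrower spectral line. The SNR gradient across subjects
  therefore arises from the line shape — the ratio of stimulus-bin power
  to the leakage into the two neighbouring bins — rather than from the
  amplitude-to-noise ratio. This matters because the coherence estimator
  and the SNR share the same data: an amplitude/noise-driven SNR gradient
  unavoidably drags the coherence of *every* uncoupled edge up with it
  (the per-bin noise fraction falls as the drive grows), which would make
  edge classes unidentifiable. With the default drift of 3.2 rad/√s every
  uncoupled pair sits near the coherence estimator's floor (about 1/K for
  K sub-windows) for all subjects, so uncoupled edges stay essentially
  flat across the entrainment gradient.
* **Coupling is phase coupling.** Planted edges share a fraction
  `ρ(g)` of their phase-noise variance: a common stream is mixed into
  both endpoint oscillators' drifts. This raises pairwise coherence at
  the stimulus bin while leaving every channel's marginal spectrum — and
  hence the SNR — exactly unchanged, so the coupling cannot feed back
  into the response measure. (An additive shared source, the obvious
  alternative, injects stimulus-band power into its endpoints: a
  `1/g`-weighted negative source then hands the *largest* stimulus power
  to the *weakest* subjects and destroys the SNR ordering.) Each
  connected component of the positive edge set shares one phase pool with
  `ρ_pos(g) = 0.95 (1.2 g)² / (1 + (1.2 g)²)`, rising with `g`; the
  default positive set consists of two fronto-parieto-occipital triangles
  (so the positively coupled sub-network has triangles and hence nonzero
  clustering) and four long-range pairs. Each negative edge has its own
  stream with `ρ_neg(g) = min(0.98, 1 − (g/2.1)³)`: near-total phase
  pooling at weak entrainment that releases steeply as `g` grows, so the
  decline outruns the mild residual rise of baseline coherence.
* **Individual variability.** Subjects differ in response topography
  (`topo_sd`), in per-channel locking quality (`jitter_het`, applied to
  the private phase stream only, so fully pooled pairs stay locked), and
  in a random background coupling structure (`bg_pools`: channels are
  reassigned to a few phase pools anew for every subject). The background
  reshuffling gives uncoupled edges genuine across-subject variability,
  without which *any* residual monotone trend — however small — becomes
  "significant" at n = 11 once the SNR ordering is clean, and the
  non-significant sub-network would be empty.

Defaults (11 subjects, entrainment factors 0.5–2, noise 0.4, gains 1.2
and 2.1) were fixed once so that planted edges are recovered with high
power at n = 11 while the false-positive rate of the edge test stays at
its nominal level under the null configuration; they are deliberately not
calibrated to any particular empirical dataset, whose inter-subject SNR
distribution is not quantitatively known.

What the generator does *not* emulate: volume conduction and a head
model, non-stationary artifacts, 1/f background spectra, harmonic
coupling structure, or realistic electrode covariance. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers the
structure it assumes — not that real recordings satisfy those
assumptions.

## Statistical and numerical choices

* **SNR averaging.** Power spectra are averaged across epochs before the
  ratio is taken. Averaging per-epoch ratios instead is ill-behaved here:
  with a two-bin noise band the per-epoch denominator is a two-sample
  exponential mean whose reciprocal has infinite variance, so epoch
  averages are dominated by occasional near-zero denominators. The
  averaged-spectrum ratio has null mean `2M/(2M−1)` over `M` epochs
  (≈ 1), which the test suite asserts against theory. A zero noise-band
  power yields `Inf`, reported as such.
* **Stimulus bin.** Always the FFT bin nearest the requested frequency;
  with the protocol windows both fundamentals are exact bins.
* **Sparsity.** Cutoff semantics: an edge survives cutoff `t` iff its
  weight is ≥ `t` (a zero weight is no edge at all); the retained-edge
  count uses round-half-up and is configurable. At sparsity 1 the
  threshold is the identity. Ties at the cut are broken by weight, then
  lexicographic node pair, for determinism.
* **Degenerate cases.** Edges with zero weight variance get an undefined
  correlation and are classified non-significant with a warning; constant
  metrics yield `NA` correlation rows rather than errors; a sub-network
  with no finite path has undefined path length (`NaN`, signalled).
* **Type-I calibration.** The acceptance suite verifies the edge
  classifier's false-positive rate against the binomial band at
  `alpha = 0.05` over 200 null cohorts, with SNR and networks estimated
  from disjoint segment halves. The split matters: with shared segments
  the oscillators' common realization noise induces a small genuine
  SNR–weight correlation under the null (measured as roughly +0.005 on
  the false-positive rate), which is a property of finite shared data,
  not of the test.
* **Reproducibility.** Every stochastic step derives from explicit
  integer seeds (per subject, per condition); generation restores the
  caller's RNG state, and identical configurations yield byte-identical
  cohorts and reports.

## Problem sizes used in validation

The shipped test suite runs the full default cohort (11 subjects × 12
segments × 2 conditions) once, 200 reduced null cohorts (6 segments) for
type-I calibration, 2000 Monte-Carlo replicates for the coherence null
bias, and 500 random small graphs for the metric oracles. These sizes
give Monte-Carlo standard errors comfortably below the tolerances they
are tested against.

## Known limitations

* Coherence on real scalp data is inflated by volume conduction; the
  pipeline deliberately mirrors a protocol that mitigates this by wide
  electrode spacing rather than by volume-conduction-robust estimators
  (imaginary coherency, phase-lag index), which are out of scope.
* The edge classification is uncorrected for multiple comparisons by
  design; its per-edge error rate is nominal but the family-wise rate
  over 153 edges is not controlled.
* With n = 11 subjects, per-edge correlations need |r| ≳ 0.6 for
  significance; effects weaker than that are invisible to the partition
  regardless of the estimator.
* The sparsity search implements the isolated-node ("sole node") stopping
  rule literally; a network can remain free of isolated nodes while
  splitting into several components, which the rule does not detect.
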