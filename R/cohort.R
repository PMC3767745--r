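#' Configuration for the synthetic steady-state cohort generator
#'
#' Describes a cohort of subjects viewing a flickering stimulus. Each
#' subject is assigned an entrainment factor `g > 0` that scales the
#' amplitude of the stimulus-locked oscillation on every channel and
#' tightens its phase locking to the stimulus: each channel's oscillator
#' carries slow random-walk phase drift with per-subject rate
#' `phase_jitter / sqrt(g)`, independent across channels, so that channel
#' pairs decohere within an epoch even though every channel is strongly
#' entrained. Stronger entrainment concentrates the oscillation into a
#' narrower spectral line, so the stimulus-band SNR increases with `g`
#' through the line shape itself, not only through amplitude.
#'
#' Planted coupling is phase coupling: the oscillators of coupled
#' channels draw a fraction `rho(g)` of their phase-drift variance from a
#' shared stream, which raises their pairwise coherence at the stimulus
#' bin without altering any channel's spectrum — and hence without
#' feeding back into the SNR. Each connected component of `pos_edges`
#' shares one phase pool whose fraction rises with `g` (connection
#' strength correlates positively with SNR across subjects); because the
#' pool couples all members pairwise, positive components must be cliques
#' (single edges and triangles qualify). Each `neg_edges` pair shares its
#' own stream whose fraction falls with `g` (anti-correlated strength,
#' emulating the sparse negatively related long-range links seen in
#' steady-state recordings).
#'
#' Set `phase_jitter = 0` for fully deterministic sinusoids (useful for
#' analytic checks: two noiseless channels are then perfectly coherent).
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param stim_freq Stimulus fundamental frequency in Hz.
#' @param fs Sampling rate in samples/s.
#' @param n_channels Number of recording channels (>= 2).
#' @param n_segments Artifact-free segments per subject.
#' @param segment_s Segment duration in seconds; `segment_s * fs` must be
#'   an integer number of samples.
#' @param entrain_factors Per-subject dimensionless gains `g > 0`; default
#'   an increasing grid from 0.5 to 2.
#' @param pos_edges,neg_edges Planted coupled node pairs, given as a
#'   two-column matrix (or list of length-2 vectors) of channel labels or
#'   indices; the two sets must be disjoint.
#' @param noise_sd Standard deviation of the independent broadband Gaussian
#'   noise added to every channel, in amplitude units.
#' @param topo_sd Log-scale standard deviation of the per-subject,
#'   per-channel amplitude topography (lognormal with mean 1): individual
#'   response topographies differ across subjects, which leaves the
#'   across-subject SNR ordering intact on average while keeping
#'   uncoupled edges from spuriously tracking the group SNR gradient.
#'   0 disables the heterogeneity.
#' @param harmonic_amp Second-harmonic amplitude as a fraction of the
#'   fundamental.
#' @param pos_gain,neg_gain Coupling gains controlling the shared
#'   phase-noise fractions:
#'   `rho_pos(g) = 0.95 (pos_gain g)^2 / (1 + (pos_gain g)^2)` (increasing
#'   in `g`) and `rho_neg(g) = min(0.98, 1 - (g / neg_gain)^3)` (releasing
#'   with `g`; `neg_gain` is the entrainment level at which the shared
#'   phase pool has fully dissolved). The summed shared fractions at any
#'   channel must stay at or below 1 for every subject.
#' @param phase_jitter Standard deviation of the random-walk phase drift in
#'   radians per square-root second at `g = 1`. 0 disables drift.
#' @param jitter_slope Exponent of the entrainment scaling of the drift
#'   rate: the per-subject rate is `phase_jitter * g^jitter_slope`. The
#'   default -1/2 makes stronger entrainment lock phase more tightly, so
#'   the SNR gradient across subjects arises from line narrowing while
#'   uncoupled channel pairs stay near the coherence floor of the
#'   estimator for every subject.
#' @param bg_pools Number of background coupling pools per subject
#'   (default 3; 0 disables). Channels are randomly assigned to pools
#'   anew for every subject and draw a random fraction of their phase
#'   noise from the pool stream, emulating individual differences in
#'   background functional connectivity; this across-subject variability
#'   keeps uncoupled edges from spuriously tracking the SNR gradient.
#' @param bg_coupling Length-2 range of the per-channel background
#'   phase-noise fraction (default `c(0.15, 0.6)`).
#' @param jitter_het Log-scale standard deviation of the per-subject,
#'   per-channel drift-rate heterogeneity (lognormal with mean 1):
#'   channels differ idiosyncratically in how tightly they lock to the
#'   stimulus, a second source of across-subject edge variability.
#'   0 disables it.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration.
#' @return An object of class `generator_config`.
#' @seealso [generate_subject()], [generate_cohort()]
#' @export
generator_config <- function(n_subjects = 11,
                             stim_freq = 12.5,
                             fs = 250,
                             n_channels = 18,
                             n_segments = 12,
                             segment_s = 6,
                             entrain_factors = seq(0.5, 2, length.out = n_subjects),
                             pos_edges = default_pos_edges(),
                             neg_edges = default_neg_edges(),
                             noise_sd = 0.4,
                             topo_sd = 0.2,
                             harmonic_amp = 0.3,
                             pos_gain = 1.2,
                             neg_gain = 2.1,
                             phase_jitter = 3.2,
                             jitter_slope = -0.5,
                             bg_pools = 3,
                             bg_coupling = c(0.1, 0.35),
                             jitter_het = 0.2,
                             seed = 1) {
  config <- list(
    n_subjects = as.integer(n_subjects), stim_freq = stim_freq, fs = fs,
    n_channels = as.integer(n_channels), n_segments = as.integer(n_segments),
    segment_s = segment_s, entrain_factors = entrain_factors,
    pos_edges = as_edge_matrix(pos_edges), neg_edges = as_edge_matrix(neg_edges),
    noise_sd = noise_sd, topo_sd = topo_sd, harmonic_amp = harmonic_amp,
    pos_gain = pos_gain, neg_gain = neg_gain,
    phase_jitter = phase_jitter, jitter_slope = jitter_slope,
    bg_pools = as.integer(bg_pools),
    bg_coupling = bg_coupling, jitter_het = jitter_het,
    seed = as.integer(seed)
  )
  config$channels <- if (config$n_channels == 18L) ssvep_montage() else
    paste0("ch", seq_len(config$n_channels))
  class(config) <- "generator_config"
  validate_generator_config(config)
  config
}

default_pos_edges <- function() {
  ## long-range fronto-parietal/occipital coupling: two closed triangles
  ## (so the positively coupled sub-network has nonzero clustering) plus
  ## four cross-region pairs; components are cliques, as the phase-pool
  ## coupling mechanism assumes
  rbind(
    c("Fp1", "P3"), c("Fp1", "O1"), c("P3", "O1"),
    c("Fp2", "P4"), c("Fp2", "O2"), c("P4", "O2"),
    c("Fz", "Pz"), c("F3", "T5"), c("F4", "T6"), c("F7", "F8")
  )
}

default_neg_edges <- function() {
  ## sparse cross-hemisphere centro-temporal pairs, disjoint from the
  ## positive set and from each other
  rbind(c("T3", "C4"), c("T4", "C3"))
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0)) {
    return(matrix(character(0), 0, 2))
  }
  if (is.list(edges)) edges <- do.call(rbind, edges)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edges must have two columns (node pairs)")
  edges
}

validate_generator_config <- function(config) {
  stopifnot(config$n_subjects >= 1, config$fs > 0, config$stim_freq > 0)
  if (config$n_channels < 2) stop("n_channels must be >= 2")
  n_samp <- config$segment_s * config$fs
  if (abs(n_samp - round(n_samp)) > 1e-8) {
    stop("segment_s * fs must be an integer number of samples")
  }
  if (length(config$entrain_factors) != config$n_subjects) {
    stop("entrain_factors must have one gain per subject")
  }
  if (any(config$entrain_factors <= 0)) {
    stop("all entrainment factors must be positive")
  }
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  pe <- resolve_edges(config$pos_edges, config$channels)
  ne <- resolve_edges(config$neg_edges, config$channels)
  if (nrow(pe) && nrow(ne) && length(intersect(key(pe), key(ne)))) {
    stop("pos_edges and neg_edges must be disjoint")
  }
  ## every positive component must be a clique (the phase pool couples
  ## all of its members pairwise), and the shared phase-noise fractions
  ## meeting at one channel must fit inside its unit variance budget
  comp <- edge_components(pe, config$n_channels)
  for (cid in unique(comp$membership[!is.na(comp$membership)])) {
    members <- which(comp$membership == cid)
    if (length(members) < 2) next
    pairs <- utils::combn(sort(members), 2)
    have <- paste(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2]))
    want <- paste(pairs[1, ], pairs[2, ])
    if (!all(want %in% have)) {
      warning("a pos_edges component is not a clique: the shared phase ",
              "pool will also couple its unlisted pairs")
    }
  }
  for (g in range(config$entrain_factors)) {
    load <- numeric(config$n_channels)
    load[!is.na(comp$membership)] <- rho_pos_fraction(g, config$pos_gain)
    for (e in seq_len(nrow(ne))) {
      load[ne[e, ]] <- load[ne[e, ]] + rho_neg_fraction(g, config$neg_gain)
    }
    if (any(load > 1 + 1e-9)) {
      stop("planted shared phase-noise fractions exceed a channel's ",
           "variance budget; reduce pos_gain/neg_gain or planted overlap")
    }
  }
  invisible(config)
}

## shared phase-noise fraction of a positive pool: rises with g
rho_pos_fraction <- function(g, pos_gain) {
  0.95 * (pos_gain * g)^2 / (1 + (pos_gain * g)^2)
}

## shared phase-noise fraction of a negative edge: near-total phase
## pooling at weak entrainment, releasing as g^3 so the decline outruns
## the tightening of per-channel phase locking at high g
rho_neg_fraction <- function(g, neg_gain) {
  pmin(0.98, pmax(0, 1 - (g / neg_gain)^3))
}

## connected components of an integer edge list over n nodes; membership
## is NA for nodes not touched by any edge
edge_components <- function(edges, n) {
  membership <- rep(NA_integer_, n)
  if (nrow(edges) == 0) return(list(membership = membership, n_comp = 0L))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
    if (ri != rj) parent[rj] <- ri
  }
  touched <- sort(unique(as.vector(edges)))
  roots <- vapply(touched, find, integer(1))
  ids <- match(roots, unique(roots))
  membership[touched] <- ids
  list(membership = membership, n_comp = length(unique(roots)))
}

## map label or index edge specs to integer channel indices
resolve_edges <- function(edges, channels) {
  if (nrow(edges) == 0) return(matrix(integer(0), 0, 2))
  idx <- apply(edges, 2, function(col) {
    suppressWarnings(num <- as.numeric(col))
    if (!anyNA(num)) return(as.integer(num))
    m <- match(col, channels)
    if (anyNA(m)) stop("unknown channel label in edge list: ",
                       paste(col[is.na(m)], collapse = ", "))
    m
  })
  idx <- matrix(as.integer(idx), ncol = 2)
  if (any(idx < 1) || any(idx > length(channels))) stop("edge index out of range")
  if (any(idx[, 1] == idx[, 2])) stop("self-edges are not allowed")
  idx
}

## deterministic per-subject, per-condition stream seed (< 2^31)
subject_seed <- function(seed, subject_index, stim_freq) {
  as.integer((as.double(seed) * 1009 + subject_index * 7919 +
                round(stim_freq * 100)) %% 2147483629)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  expr
}

row_cumsum <- function(m) {
  if (ncol(m) == 0) return(m)
  t(apply(m, 1, cumsum))
}

#' Generate one subject's recording
#'
#' Synthesizes `n_segments` segments of `n_channels x (segment_s * fs)`
#' data for one subject. Each channel carries a stimulus-locked oscillation
#' at `stim_freq` with amplitude equal to the subject's entrainment factor
#' `g` (plus an optional second harmonic) and slow random-walk phase
#' drift. Channel pairs in `pos_edges`/`neg_edges` share part of their
#' phase-drift variance (the shared fraction increases with `g` on
#' positive edges and decreases with `g` on negative edges; see
#' [generator_config()]), which couples their coherence at the stimulus
#' bin without changing any channel's spectrum. Independent Gaussian
#' broadband noise of standard deviation `noise_sd` is added throughout.
#'
#' @param config A [generator_config()].
#' @param subject_index Subject number in `1:n_subjects`.
#' @return An object of class `recording`: a list with `segments` (list of
#'   channel-by-sample matrices), `fs`, `stim_freq`, `channels`, `subject`
#'   and the subject's `entrain` factor.
#' @export
generate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  if (subject_index < 1 || subject_index > config$n_subjects) {
    stop("subject_index must be in 1:n_subjects")
  }
  g <- config$entrain_factors[subject_index]
  fs <- config$fs
  f0 <- config$stim_freq
  n <- as.integer(round(config$segment_s * fs))
  C <- config$n_channels
  tt <- (seq_len(n) - 1) / fs
  base <- matrix(2 * pi * f0 * tt, C, n, byrow = TRUE)
  pe <- resolve_edges(config$pos_edges, config$channels)
  ne <- resolve_edges(config$neg_edges, config$channels)
  comp <- edge_components(pe, C)
  rho_pos <- rho_pos_fraction(g, config$pos_gain)
  rho_neg <- rho_neg_fraction(g, config$neg_gain)
  ## per-channel phase-noise variance committed to planted coupling
  planted <- numeric(C)
  planted[!is.na(comp$membership)] <- rho_pos
  for (e in seq_len(nrow(ne))) planted[ne[e, ]] <- planted[ne[e, ]] + rho_neg
  ## per-subject drift rate scales as g^jitter_slope (default -1/2:
  ## stronger entrainment locks phase more tightly)
  drift <- config$phase_jitter * g^config$jitter_slope / sqrt(fs)

  with_preserved_rng({
    set.seed(subject_seed(config$seed, subject_index, f0))
    phi <- stats::runif(C, 0, 2 * pi)
    phih <- stats::runif(C, 0, 2 * pi)
    ## subject-specific response topography (lognormal, mean 1)
    topo <- if (config$topo_sd > 0) {
      exp(stats::rnorm(C, 0, config$topo_sd) - config$topo_sd^2 / 2)
    } else {
      rep(1, C)
    }
    ## idiosyncratic per-channel locking quality: each channel's drift
    ## rate is scaled by a subject-specific lognormal factor
    drift_c <- if (config$jitter_het > 0) {
      drift * exp(stats::rnorm(C, 0, config$jitter_het) -
                    config$jitter_het^2 / 2)
    } else {
      rep(drift, C)
    }
    ## subject-specific background coupling: random pool membership and
    ## per-channel fractions, redrawn for every subject
    if (config$bg_pools > 0) {
      bg_pool <- sample.int(config$bg_pools, C, replace = TRUE)
      bg_rho <- stats::runif(C, config$bg_coupling[1], config$bg_coupling[2])
      bg_rho <- pmin(bg_rho, pmax(0, 1 - planted))
    } else {
      bg_pool <- integer(C)
      bg_rho <- numeric(C)
    }
    private <- pmax(0, 1 - planted - bg_rho)
    segments <- vector("list", config$n_segments)
    for (s in seq_len(config$n_segments)) {
      ## phase-drift increments from unit-variance streams. The private
      ## stream carries the channel's idiosyncratic drift rate; shared
      ## streams use the subject-level rate on every member, so that a
      ## fully pooled pair stays phase-locked regardless of heterogeneity.
      inc <- (drift_c * sqrt(private)) * matrix(stats::rnorm(C * n), C, n)
      for (cid in seq_len(comp$n_comp)) {
        pool <- stats::rnorm(n) * (drift * sqrt(rho_pos))
        members <- which(!is.na(comp$membership) & comp$membership == cid)
        for (m in members) inc[m, ] <- inc[m, ] + pool
      }
      for (e in seq_len(nrow(ne))) {
        shared <- stats::rnorm(n) * (drift * sqrt(rho_neg))
        inc[ne[e, 1], ] <- inc[ne[e, 1], ] + shared
        inc[ne[e, 2], ] <- inc[ne[e, 2], ] + shared
      }
      if (config$bg_pools > 0) {
        for (b in seq_len(config$bg_pools)) {
          stream <- stats::rnorm(n)
          members <- which(bg_pool == b)
          for (m in members) {
            inc[m, ] <- inc[m, ] + (drift * sqrt(bg_rho[m])) * stream
          }
        }
      }
      theta <- row_cumsum(inc)
      thetah <- row_cumsum(drift_c * matrix(stats::rnorm(C * n), C, n))
      x <- (g * topo) * cos(base + phi + theta) +
        (config$harmonic_amp * g * topo) * cos(2 * base + phih + thetah)
      x <- x + matrix(stats::rnorm(C * n, 0, config$noise_sd), C, n)
      rownames(x) <- config$channels
      segments[[s]] <- x
    }
    structure(
      list(segments = segments, fs = fs, stim_freq = f0,
           channels = config$channels, subject = as.integer(subject_index),
           entrain = g),
      class = "recording"
    )
  })
}

#' Generate a full synthetic cohort with ground truth
#'
#' Calls [generate_subject()] for every subject and returns the recordings
#' together with the generating ground truth (entrainment factors and the
#' planted class of every unordered channel pair). The cohort is a pure
#' function of the configuration: the same `config` (including its seed)
#' always yields a bit-identical cohort, and the global RNG state is left
#' untouched.
#'
#' @param config A [generator_config()].
#' @return A list with `recordings` (list of `recording` objects) and
#'   `truth`, a list holding `entrain_factors` and `edge_class`, a
#'   data frame with one row per unordered channel pair and columns
#'   `node_i`, `node_j`, `class` (`"positive"`, `"negative"` or `"null"`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  recordings <- lapply(seq_len(config$n_subjects),
                       function(i) generate_subject(config, i))
  list(recordings = recordings, truth = cohort_truth(config))
}

cohort_truth <- function(config) {
  ch <- config$channels
  pairs <- which(upper.tri(diag(length(ch))), arr.ind = TRUE)
  cls <- rep("null", nrow(pairs))
  mark <- function(edges, label) {
    idx <- resolve_edges(edges, ch)
    for (e in seq_len(nrow(idx))) {
      i <- min(idx[e, ]); j <- max(idx[e, ])
      cls[pairs[, 1] == i & pairs[, 2] == j] <<- label
    }
  }
  mark(config$pos_edges, "positive")
  mark(config$neg_edges, "negative")
  list(
    entrain_factors = config$entrain_factors,
    edge_class = data.frame(node_i = ch[pairs[, 1]], node_j = ch[pairs[, 2]],
                            class = cls, stringsAsFactors = FALSE)
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: subject %d, %d segments of %d channels x %d samples (fs = %g Hz, stimulus %.4g Hz)\n",
              x$subject, length(x$segments), nrow(x$segments[[1]]),
              ncol(x$segments[[1]]), x$fs, x$stim_freq))
  invisible(x)
}
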