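#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults follow the
#' standard protocol: 2.4 s epochs with 1.2 s overlap, 1.2 s coherence
#' sub-windows with 50% overlap, a 0.01 sparsity-search step, uncorrected
#' alpha 0.05 for edge classification, 5000 permutations (exact
#' enumeration is substituted automatically when feasible) and the two
#' flicker frequencies 12.5 Hz and 16.67 Hz derived from 80 ms and 60 ms
#' cycles.
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read
#'   recordings from manifests).
#' @param generator A [generator_config()] used in synthetic mode; its
#'   `stim_freq` and `seed` are overridden per condition from
#'   `stim_freqs` and `seed`.
#' @param manifests In files mode, a list (one element per condition) of
#'   character vectors of manifest paths, one manifest per subject.
#' @param stim_freqs Stimulus frequencies in Hz (each > 4, the steady-state
#'   regime).
#' @param window_s,overlap_s Epoch window and overlap in seconds.
#' @param subwindow_s,sub_overlap Coherence sub-window length (s) and
#'   fractional overlap.
#' @param band_hz SNR noise-band width in Hz.
#' @param sparsity_step Cutoff step of the sparsity search.
#' @param alpha Uncorrected significance level for edge classification.
#' @param n_perm Permutation count for the two-group test.
#' @param n_group Group size for the high/low-SNR comparison.
#' @param seed Master seed; all randomness derives from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            generator = generator_config(),
                            manifests = NULL,
                            stim_freqs = c(stim_frequency(80), stim_frequency(60)),
                            window_s = 2.4, overlap_s = 1.2,
                            subwindow_s = 1.2, sub_overlap = 0.5,
                            band_hz = 1,
                            sparsity_step = 0.01, alpha = 0.05,
                            n_perm = 5000, n_group = 4, seed = 1) {
  mode <- match.arg(mode)
  if (any(stim_freqs <= 4)) {
    stop("steady-state stimulus frequencies must exceed 4 Hz")
  }
  if (window_s <= overlap_s) stop("window_s must exceed overlap_s")
  if (mode == "files" && is.null(manifests)) {
    stop("files mode requires 'manifests'")
  }
  structure(list(mode = mode, generator = generator, manifests = manifests,
                 stim_freqs = stim_freqs, window_s = window_s,
                 overlap_s = overlap_s, subwindow_s = subwindow_s,
                 sub_overlap = sub_overlap, band_hz = band_hz,
                 sparsity_step = sparsity_step, alpha = alpha,
                 n_perm = n_perm, n_group = n_group, seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full network-topology analysis pipeline
#'
#' Executes, per stimulus condition: cohort generation (or loading),
#' epoch extraction, SNR computation, per-epoch coherence and averaging
#' into each subject's original whole network. The sparsity value is then
#' searched over the original networks of all conditions pooled, each
#' network is thresholded to Network 0, edges are classified by their
#' across-subject correlation with SNR into Networks 1/2/3, weighted
#' topology metrics are computed for Networks 0, 1 and 2 (Network 3 is
#' kept as a sub-network but its metrics are not computed since it is
#' typically very sparse), metric-SNR correlation tables are assembled,
#' and the high-SNR versus low-SNR edge-wise permutation test is run.
#' The run is a pure function of the configuration.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory; when given, edge lists,
#'   metric/correlation/permutation CSV tables and a JSON summary are
#'   written there.
#' @param verbose Emit stage-level progress messages.
#' @return An object of class `ssvep_report`: list with `sparsity`,
#'   per-condition results (`snr`, `networks0`, `partition`, `metrics`,
#'   `correlations`, `permutation`, `truth` in synthetic mode) and the
#'   pooled `metrics` and `correlations` tables.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  conditions <- vapply(config$stim_freqs, condition_label, character(1))
  per_cond <- vector("list", length(conditions))
  names(per_cond) <- conditions

  for (ci in seq_along(config$stim_freqs)) {
    f0 <- config$stim_freqs[ci]
    pipeline_log(verbose, "[%s] loading/generating recordings", conditions[ci])
    if (config$mode == "synthetic") {
      gc <- config$generator
      gc$stim_freq <- f0
      gc$seed <- config$seed
      validate_generator_config(gc)
      cohort <- generate_cohort(gc)
      recordings <- cohort$recordings
      truth <- cohort$truth
    } else {
      recordings <- lapply(config$manifests[[ci]], read_recording)
      truth <- NULL
    }
    pipeline_log(verbose, "[%s] %d subjects, %d segments each", conditions[ci],
                 length(recordings), length(recordings[[1]]$segments))
    snr <- vapply(recordings, function(rec) {
      recording_snr(rec, stim_freq = f0, window_s = config$window_s,
                    overlap_s = config$overlap_s,
                    band_hz = config$band_hz)$mean_snr
    }, numeric(1))
    originals <- lapply(recordings, recording_network, stim_freq = f0,
                        window_s = config$window_s,
                        overlap_s = config$overlap_s,
                        subwindow_s = config$subwindow_s,
                        sub_overlap = config$sub_overlap)
    pipeline_log(verbose, "[%s] averaged %d-epoch coherence networks",
                 conditions[ci], originals[[1]]$n_epochs)
    per_cond[[ci]] <- list(stim_freq = f0, snr = snr, originals = originals,
                           truth = truth)
  }

  ## sparsity from the original whole networks of all conditions pooled
  all_orig <- unlist(lapply(per_cond, `[[`, "originals"), recursive = FALSE)
  spars <- find_sparsity(all_orig, step = config$sparsity_step)
  pipeline_log(verbose, "sparsity %.2f (%d of %d edges kept)", spars$sparsity,
               spars$n_edges_kept, spars$n_possible)

  metrics_rows <- list()
  corr_rows <- list()
  for (ci in seq_along(per_cond)) {
    pc <- per_cond[[ci]]
    cond <- conditions[ci]
    networks0 <- lapply(pc$originals, apply_sparsity, sparsity = spars$sparsity)
    corr <- edgewise_correlation(networks0, pc$snr)
    partition <- classify_edges(corr, alpha = config$alpha)
    subnets <- lapply(c(positive = "positive", nonsig = "nonsig",
                        negative = "negative"), function(cls) {
      lapply(networks0, subnetwork, partition = partition, cls = cls)
    })
    nets_by_id <- list(`0` = networks0, `1` = subnets$positive,
                       `2` = subnets$nonsig)
    for (id in names(nets_by_id)) {
      for (s in seq_along(nets_by_id[[id]])) {
        tm <- topology_metrics(nets_by_id[[id]][[s]])
        metrics_rows[[length(metrics_rows) + 1]] <- data.frame(
          subject = s, condition = cond, network_id = as.integer(id),
          clustering = tm$clustering, path_length = tm$path_length,
          global_eff = tm$global_eff, local_eff = tm$local_eff,
          mean_connectivity = tm$mean_connectivity, n_edges = tm$n_edges,
          snr = pc$snr[s], stringsAsFactors = FALSE)
      }
      mtab <- do.call(rbind, metrics_rows[
        vapply(metrics_rows, function(r)
          r$condition == cond && r$network_id == as.integer(id), logical(1))])
      corr_rows[[length(corr_rows) + 1]] <-
        metric_snr_correlations(mtab, pc$snr, condition = cond,
                                network_id = as.integer(id))
    }
    groups <- split_groups_by_snr(networks0, pc$snr, k = config$n_group)
    perm <- group_permutation_test(groups$high, groups$low,
                                   n_perm = config$n_perm,
                                   seed = config$seed + ci)
    pipeline_log(verbose, "[%s] permutation test (%s, %d resamples)", cond,
                 attr(perm, "method"), attr(perm, "n_perm"))
    per_cond[[ci]] <- c(pc, list(networks0 = networks0, corr = corr,
                                 partition = partition, subnets = subnets,
                                 permutation = perm, groups = groups))
  }

  metrics <- do.call(rbind, metrics_rows)
  correlations <- do.call(rbind, corr_rows)
  report <- structure(list(sparsity = spars, conditions = per_cond,
                           metrics = metrics, correlations = correlations,
                           config = config),
                      class = "ssvep_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.ssvep_report <- function(x, ...) {
  cat(sprintf("ssvep_report: %d condition(s), %d subjects, sparsity %.2f\n",
              length(x$conditions), length(x$conditions[[1]]$snr),
              x$sparsity$sparsity))
  for (cond in names(x$conditions)) {
    pc <- x$conditions[[cond]]
    tab <- table(factor(pc$partition$edges$class,
                        c("positive", "nonsig", "negative")))
    cat(sprintf("  %s: mean SNR %.2f-%.2f; edges: %d positive, %d nonsig, %d negative\n",
                cond, min(pc$snr), max(pc$snr), tab[["positive"]],
                tab[["nonsig"]], tab[["negative"]]))
  }
  invisible(x)
}

#' Write all report tables to a directory
#'
#' Emits per-subject Network 0 edge lists, the partition edge table, the
#' metrics, correlation and permutation CSV tables, and a JSON summary.
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$metrics, file.path(outdir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlations, file.path(outdir, "correlations.csv"),
                   row.names = FALSE)
  for (cond in names(report$conditions)) {
    pc <- report$conditions[[cond]]
    utils::write.csv(pc$partition$edges,
                     file.path(outdir, sprintf("partition_%s.csv", cond)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(pc$permutation),
                     file.path(outdir, sprintf("permutation_%s.csv", cond)),
                     row.names = FALSE)
    for (s in seq_along(pc$networks0)) {
      write_edge_list(pc$networks0[[s]],
                      file.path(outdir, sprintf("network0_%s_sub%02d.csv",
                                                cond, s)))
    }
  }
  summary <- list(
    sparsity = report$sparsity$sparsity,
    critical_threshold = report$sparsity$critical_threshold,
    n_edges_kept = report$sparsity$n_edges_kept,
    conditions = lapply(report$conditions, function(pc) {
      list(stim_freq = pc$stim_freq, mean_snr = pc$snr,
           edge_classes = as.list(table(pc$partition$edges$class)))
    })
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
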