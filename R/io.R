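#' Write a recording as delimited matrices plus a JSON manifest
#'
#' Each segment is written as one tab-delimited text matrix (channels in
#' rows, samples in columns, no headers); the manifest records subject,
#' condition, sampling rate, channel labels and the segment file names.
#'
#' @param recording A `recording` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `sub<subject>_<condition>`.
#' @return Invisibly, the manifest path.
#' @export
write_recording <- function(recording, dir, prefix = NULL) {
  if (is.null(prefix)) {
    prefix <- sprintf("sub%02d_%s", recording$subject,
                      condition_label(recording$stim_freq))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_seg%02d.txt", prefix, seq_along(recording$segments))
  for (s in seq_along(recording$segments)) {
    utils::write.table(recording$segments[[s]], file.path(dir, files[s]),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  manifest <- list(subject = recording$subject,
                   condition = condition_label(recording$stim_freq),
                   stim_freq = recording$stim_freq, fs = recording$fs,
                   channels = recording$channels, segments = files)
  path <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a recording from a JSON manifest
#'
#' Counterpart of [write_recording()]: loads the segment matrices listed
#' in the manifest (paths resolved relative to the manifest's directory).
#'
#' @param manifest_path Path to the manifest JSON file.
#' @return A `recording` object.
#' @export
read_recording <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  segments <- lapply(man$segments, function(f) {
    m <- as.matrix(utils::read.table(file.path(dir, f), sep = "\t",
                                     header = FALSE))
    dimnames(m) <- list(man$channels, NULL)
    m
  })
  structure(list(segments = segments, fs = man$fs, stim_freq = man$stim_freq,
                 channels = man$channels,
                 subject = if (is.null(man$subject)) NA_integer_ else man$subject,
                 entrain = NA_real_),
            class = "recording")
}

#' Write a synthetic cohort to disk
#'
#' Writes every subject's recording via [write_recording()] and the
#' generating ground truth (entrainment factors and planted edge classes)
#' as JSON.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return Invisibly, the vector of manifest paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$recordings, write_recording, character(1), dir = dir)
  jsonlite::write_json(
    list(entrain_factors = cohort$truth$entrain_factors,
         edge_class = cohort$truth$edge_class),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(paths)
}

## edge-list data frame of a network's nonzero edges
network_edge_list <- function(network) {
  w <- net_weights(network)
  labels <- rownames(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  data.frame(node_i = labels[ut[, 1]], node_j = labels[ut[, 2]],
             weight = w[ut], stringsAsFactors = FALSE)
}

write_edge_list <- function(network, path) {
  utils::write.csv(network_edge_list(network), path, row.names = FALSE)
  invisible(path)
}
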