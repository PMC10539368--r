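# File-format plumbing: TIFF trial stacks with a YAML session manifest,
# CSV tables, JSON ground-truth sidecars.

#' Write a dual-channel trial set to TIFF + manifest
#'
#' One 16-bit multi-frame TIFF per trial per channel, a YAML session
#' manifest (frame rate, stimulus onset, channel labels, intensity
#' scale), and a JSON ground-truth sidecar when present.
#'
#' @param trialset A `bq_trialset`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_trialset_tiff <- function(trialset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mx <- max(vapply(trialset$trials, function(tr) {
    max(tr$ch465, tr$ch405)
  }, numeric(1)))
  scale <- mx * 1.05
  files <- list()
  for (i in seq_along(trialset$trials)) {
    for (ch in c("ch465", "ch405")) {
      stack <- trialset$trials[[i]][[ch]]
      frames <- lapply(seq_len(dim(stack)[1]), function(k) {
        pmin(pmax(stack[k, , ] / scale, 0), 1)
      })
      f <- file.path(dir, sprintf("trial%03d_%s.tif", i, ch))
      tiff::writeTIFF(frames, f, bits.per.sample = 16)
      files[[sprintf("trial%03d_%s", i, ch)]] <- basename(f)
    }
  }
  manifest <- list(
    frame_rate = trialset$frame_rate,
    stimulus_onset = trialset$stimulus_onset,
    channel_offset_s = trialset$channel_offset_s,
    pixel_size_um = trialset$pixel_size_um,
    n_trials = length(trialset$trials),
    intensity_scale = scale,
    channels = c("ch465", "ch405"),
    files = files
  )
  mpath <- file.path(dir, "session.yaml")
  yaml::write_yaml(manifest, mpath)
  gt <- attr(trialset, "ground_truth", exact = TRUE)
  if (!is.null(gt)) write_ground_truth(gt, file.path(dir, "ground_truth.json"))
  invisible(mpath)
}

#' Read a dual-channel trial set from a session manifest
#'
#' @param manifest_path Path to the `session.yaml` written by
#'   [write_trialset_tiff()].
#' @return A `bq_trialset`.
#' @export
read_trialset_tiff <- function(manifest_path) {
  m <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  trials <- lapply(seq_len(m$n_trials), function(i) {
    read_stack <- function(ch) {
      frames <- tiff::readTIFF(
        file.path(dir, m$files[[sprintf("trial%03d_%s", i, ch)]]),
        all = TRUE
      )
      arr <- array(0, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
      for (k in seq_along(frames)) arr[k, , ] <- frames[[k]] * m$intensity_scale
      arr
    }
    list(ch465 = read_stack("ch465"), ch405 = read_stack("ch405"))
  })
  n_frames <- dim(trials[[1]]$ch465)[1]
  structure(
    list(trials = trials, frame_rate = m$frame_rate,
         stimulus_onset = m$stimulus_onset,
         time = (seq_len(n_frames) - 1) / m$frame_rate,
         channel_offset_s = m$channel_offset_s,
         pixel_size_um = m$pixel_size_um, n_trials = m$n_trials),
    class = "bq_trialset"
  )
}

#' Write a tibble to CSV (stable field order, no row names)
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
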