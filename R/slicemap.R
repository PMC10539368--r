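# Photostimulation input maps: EPSC event detection in a post-stimulus
# window, per-site summed amplitudes, and laminar/columnar binning.

#' Detect EPSC events in a post-stimulus window
#'
#' Scans a current trace for inward (negative) deflections whose peaks
#' exceed `threshold` (pA) relative to the pre-stimulus baseline, with
#' onsets inside the analysis window (150 ms after the stimulus by
#' default). An early-latency veto window (7 ms by default) excludes
#' direct photostimulation responses at the soma.
#'
#' @param trace Current trace in pA (inward negative).
#' @param sample_rate Sampling rate in Hz.
#' @param stimulus_time Stimulus time in seconds from sweep start.
#' @param window Analysis window length after the stimulus, seconds.
#' @param threshold Detection threshold in pA; `NULL` uses 3 x the
#'   pre-stimulus baseline SD (or 1 pA for noise-free traces).
#' @param veto Early-latency veto window after the stimulus, seconds (0
#'   disables it).
#' @param min_separation Minimum peak separation in seconds.
#' @return A tibble (`time`, `latency`, `amplitude`) of event peaks;
#'   amplitudes are positive inward magnitudes.
#' @export
detect_epsc_events <- function(trace, sample_rate, stimulus_time,
                               window = 0.15, threshold = NULL,
                               veto = 0.007, min_separation = 0.005) {
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  n <- length(trace)
  t <- (seq_len(n) - 1) / sample_rate
  if (stimulus_time + window > t[n] + 1e-9) {
    abort("Analysis window extends beyond the sweep.")
  }
  pre <- t < stimulus_time
  baseline <- if (any(pre)) median(trace[pre]) else 0
  if (is.null(threshold)) {
    bsd <- if (any(pre)) sd(trace[pre]) else 0
    threshold <- if (is.finite(bsd) && bsd > 0) 3 * bsd else 1
  }
  y <- baseline - trace  # inward magnitude, positive
  in_win <- t > stimulus_time + veto & t <= stimulus_time + window
  # local maxima above threshold inside the window
  cand <- which(in_win & y > threshold)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[y[cand] >= y[cand - 1] & y[cand] >= y[cand + 1]]
  if (length(cand) == 0) {
    return(tibble(time = numeric(), latency = numeric(),
                  amplitude = numeric()))
  }
  # greedy non-maximum suppression by amplitude within min_separation
  ord <- cand[order(-y[cand])]
  keep <- integer()
  min_gap <- min_separation * sample_rate
  for (i in ord) {
    if (all(abs(i - keep) >= min_gap)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  tibble(time = t[keep], latency = t[keep] - stimulus_time,
         amplitude = y[keep])
}

#' Build a per-site input map from a photostimulation recording
#'
#' Detects EPSC events in each site's trace and assigns the site the sum
#' of detected event peak amplitudes (pA). The map is invariant to the
#' (quasi-random) site acquisition order.
#'
#' @param recording A `bq_photostim` object (see [simulate_epsc_grid()])
#'   or a list with `traces` (site x sample matrix), `sites` tibble,
#'   `sample_rate`, `stimulus_time`.
#' @param ... Passed to [detect_epsc_events()].
#' @return A tibble of class `bq_input_map` (`site`, `row`, `col`,
#'   `amplitude`, `n_events`); sites with missing traces are `NA` and
#'   flagged in `missing`.
#' @export
build_input_map <- function(recording, ...) {
  tr <- recording$traces
  sites <- recording$sites
  amps <- rep(NA_real_, nrow(sites))
  nev <- rep(NA_integer_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    trace <- tr[sites$site[i], ]
    if (anyNA(trace)) next
    ev <- detect_epsc_events(trace, recording$sample_rate,
                             recording$stimulus_time, ...)
    amps[i] <- sum(ev$amplitude)
    nev[i] <- nrow(ev)
  }
  out <- tibble(site = sites$site, row = sites$row, col = sites$col,
                amplitude = amps, n_events = nev,
                missing = is.na(amps))
  if (any(out$missing)) warn("Sites with missing traces flagged NA.")
  class(out) <- c("bq_input_map", class(out))
  out
}

#' Laminar / columnar binning of an input map
#'
#' Labels every stimulation site with its cortical layer (from laminar
#' borders along the grid's row axis) and whether it lies inside the
#' recorded cell's home column, then averages the per-site summed EPSC
#' amplitude within each layer for intracolumnar and transcolumnar sites
#' separately.
#'
#' @param map A `bq_input_map` (from [build_input_map()]).
#' @param laminar_borders Named numeric vector of layer upper boundaries
#'   in grid-row units, ordered pia to white matter, e.g.
#'   `c(L1 = 2, `L2/3` = 6, L4 = 9, L5a = 11, L5b = 13, L6 = 15)`: layer
#'   `k` spans rows `(border[k-1], border[k]]`.
#' @param home_column `c(first, last)` column indices of the home column.
#' @return A tibble (`layer`, `compartment`, `mean_amplitude`,
#'   `n_sites`); empty layer/compartment cells are `NA` and flagged in
#'   `missing`.
#' @export
bin_input_map <- function(map, laminar_borders, home_column) {
  if (is.null(names(laminar_borders)) || is.unsorted(laminar_borders)) {
    abort("`laminar_borders` must be a named, increasing vector.")
  }
  if (max(map$row) > max(laminar_borders)) {
    abort("Laminar borders do not cover the grid.")
  }
  layers <- names(laminar_borders)
  lab <- layers[findInterval(map$row, c(0, laminar_borders),
                             left.open = TRUE, rightmost.closed = TRUE)]
  intra <- map$col >= home_column[1] & map$col <= home_column[2]
  df <- tibble(layer = factor(lab, levels = layers),
               compartment = ifelse(intra, "intracolumnar", "transcolumnar"),
               amplitude = map$amplitude)
  out <- tidyr::complete(
    dplyr::summarise(
      dplyr::group_by(df, .data$layer, .data$compartment),
      mean_amplitude = mean(.data$amplitude, na.rm = TRUE),
      n_sites = dplyr::n(), .groups = "drop"
    ),
    layer = factor(layers, levels = layers),
    compartment = c("intracolumnar", "transcolumnar"),
    fill = list(mean_amplitude = NA_real_, n_sites = 0L)
  )
  out$mean_amplitude[is.nan(out$mean_amplitude)] <- NA_real_
  out$missing <- out$n_sites == 0 | is.na(out$mean_amplitude)
  out
}
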