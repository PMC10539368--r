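# Widefield calcium-imaging chain: binning, detrending/filtering,
# dual-wavelength hemodynamic correction, dF/F, trial averaging, response
# metrics and evoked-area measurement.

#' Spatially bin a frame or frame stack
#'
#' Each output pixel is the mean of its `factor` x `factor` block
#' (4 x 4 by default, taking e.g. 880 x 800 raw frames to 220 x 200).
#' Trailing rows/columns that do not fill a block are cropped (with a
#' message). The frame count of a stack is unchanged, and when dimensions
#' divide evenly the global frame mean is conserved exactly.
#'
#' @param x A matrix (`[y, x]`) or 3-D array (`[frame, y, x]`).
#' @param factor Integer binning factor (>= 1).
#' @return Binned matrix or array.
#' @export
spatial_bin <- function(x, factor = 4) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor)) {
    abort("`factor` must be a positive integer.")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(x)
  bin2d <- function(m) {
    h <- nrow(m) %/% factor * factor
    w <- ncol(m) %/% factor * factor
    if (h < nrow(m) || w < ncol(m)) {
      message(sprintf("spatial_bin: cropping %dx%d frame to %dx%d.",
                      nrow(m), ncol(m), h, w))
      m <- m[seq_len(h), seq_len(w), drop = FALSE]
    }
    if (h < factor || w < factor) abort("Frame smaller than one block.")
    tmp <- colMeans(array(m, c(factor, h %/% factor, w)))     # [h/f, w]
    t(colMeans(array(t(tmp), c(factor, w %/% factor, h %/% factor))))
  }
  if (is.matrix(x)) return(bin2d(x))
  if (length(dim(x)) == 3) {
    first <- bin2d(x[1, , ])
    out <- array(NA_real_, c(dim(x)[1], nrow(first), ncol(first)))
    out[1, , ] <- first
    if (dim(x)[1] > 1) {
      for (k in 2:dim(x)[1]) out[k, , ] <- suppressMessages(bin2d(x[k, , ]))
    }
    return(out)
  }
  abort("`x` must be a matrix or a [frame, y, x] array.")
}

#' Detrend and band-pass filter a fluorescence time series
#'
#' Removes the least-squares linear trend, then applies a second-order
#' Butterworth high-pass (0.01 Hz) followed by a second-order low-pass
#' (10 Hz), both zero-phase (forward-backward) so that response latencies
#' are unbiased.
#'
#' @param x Numeric time series.
#' @param frame_rate Sampling rate in Hz; must exceed twice the low-pass
#'   cutoff.
#' @param high,low High-/low-pass cutoffs in Hz.
#' @param trend_window Optional logical/integer index of the samples used
#'   to fit the linear trend (extrapolated over the whole series). The
#'   default fits all samples; pipelines fit the pre-stimulus window only
#'   so the evoked response is not regressed out.
#' @return Filtered series of the same length.
#' @export
preprocess_trace <- function(x, frame_rate, high = 0.01, low = 10,
                             trend_window = NULL) {
  if (length(x) < 3) abort("Series must contain at least 3 samples.")
  check_number(frame_rate, "frame_rate", 0, strict = TRUE)
  if (frame_rate <= 2 * low) {
    abort("`frame_rate` must exceed twice the low-pass cutoff.")
  }
  t <- seq_along(x)
  w <- if (is.null(trend_window)) t else t[trend_window]
  if (length(w) < 2) abort("`trend_window` must select at least 2 samples.")
  fit <- lm.fit(cbind(1, w), x[w])
  y <- x - cbind(1, t) %*% fit$coefficients
  if (length(y) >= 12) {
    bh <- signal::butter(2, high / (frame_rate / 2), type = "high")
    y <- signal::filtfilt(bh, y)
    bl <- signal::butter(2, low / (frame_rate / 2), type = "low")
    y <- signal::filtfilt(bl, y)
  } else {
    warn("Series too short for stable zero-phase filtering; detrend only.")
  }
  as.numeric(y)
}

# Detrend + band-pass every pixel of a [frame, y, x] stack, then re-add the
# per-pixel temporal mean so that baseline fluorescence (and hence F0)
# remains meaningful downstream.
preprocess_stack <- function(stack, frame_rate, high = 0.01, low = 10,
                             trend_window = NULL) {
  d <- dim(stack)
  m <- matrix(stack, d[1], d[2] * d[3])
  mu <- colMeans(m)
  t <- seq_len(d[1])
  w <- if (is.null(trend_window)) t else t[trend_window]
  Xw <- cbind(1, w)
  beta <- solve(crossprod(Xw), crossprod(Xw, m[w, , drop = FALSE]))
  res <- m - cbind(1, t) %*% beta
  bh <- signal::butter(2, high / (frame_rate / 2), type = "high")
  bl <- signal::butter(2, low / (frame_rate / 2), type = "low")
  res <- filtfilt_mat(bl$b, bl$a, filtfilt_mat(bh$b, bh$a, res))
  out <- sweep(res, 2, mu, "+")
  array(out, d)
}

#' Dual-wavelength hemodynamic correction
#'
#' Scales the calcium-insensitive 405 nm stack by the per-pixel ratio of
#' temporal means, `scale[y,x] = mean_t(465) / mean_t(405)`, and subtracts
#' it from the 465 nm stack:
#' `corrected[t,y,x] = ch465[t,y,x] - scale[y,x] * ch405[t,y,x]`.
#' Identical channels therefore map to zero, and the result is invariant
#' to rescaling the 405 channel by any positive constant. Pixels whose
#' 405 nm temporal mean is zero are masked `NA` (with a warning).
#'
#' @param ch465,ch405 Arrays `[frame, y, x]` (or plain time-series
#'   vectors) of identical shape.
#' @return Corrected array with the scale map attached as attribute
#'   `"scale"`.
#' @export
hemodynamic_correct <- function(ch465, ch405) {
  if (!identical(dim(ch465), dim(ch405)) ||
      length(ch465) != length(ch405)) {
    abort("Channel stacks must have identical shape.")
  }
  if (is.null(dim(ch465))) {
    m465 <- mean(ch465)
    m405 <- mean(ch405)
    if (m405 == 0) abort("405 nm temporal mean is zero.")
    out <- ch465 - (m465 / m405) * ch405
    attr(out, "scale") <- m465 / m405
    return(out)
  }
  m465 <- apply(ch465, c(2, 3), mean)
  m405 <- apply(ch405, c(2, 3), mean)
  scale <- m465 / m405
  bad <- m405 == 0
  if (any(bad)) {
    warn(sprintf("%d pixel(s) with zero 405 nm mean masked NA.", sum(bad)))
    scale[bad] <- NA_real_
  }
  out <- ch465 - aperm(
    array(scale, c(dim(scale), dim(ch465)[1])), c(3, 1, 2)
  ) * ch405
  attr(out, "scale") <- scale
  out
}

#' Fractional fluorescence change relative to the pre-stimulus baseline
#'
#' `dff[t] = (F[t] - F0) / F0`, with `F0` the mean over the
#' `pre_window`-second window ending at stimulus onset (500 ms by
#' default). For a corrected stack whose own baseline hovers near zero,
#' pass the reference-channel baseline via `f0`.
#'
#' @param x Numeric trace or `[frame, y, x]` array.
#' @param frame_rate Sampling rate in Hz (frame k is at time
#'   `(k - 1) / frame_rate`).
#' @param stimulus_onset Stimulus time in seconds from trace start.
#' @param pre_window Baseline window length in seconds.
#' @param f0 Optional externally supplied baseline (scalar for a trace,
#'   matrix for a stack); when `NULL` the pre-stimulus mean of `x` is used.
#' @return For a trace, a `bq_response_trace` tibble with columns `time`
#'   and `dff` and attributes `stimulus_onset` and `f0`; for a stack, a
#'   dF/F array with the same attributes.
#' @export
compute_dff <- function(x, frame_rate, stimulus_onset, pre_window = 0.5,
                        f0 = NULL) {
  check_number(frame_rate, "frame_rate", 0, strict = TRUE)
  check_number(stimulus_onset, "stimulus_onset", 0)
  n <- if (is.null(dim(x))) length(x) else dim(x)[1]
  t <- (seq_len(n) - 1) / frame_rate
  pre <- t < stimulus_onset & t >= stimulus_onset - pre_window
  if (is.null(f0) && !any(pre)) {
    abort("No samples fall inside the pre-stimulus window.")
  }
  if (is.null(dim(x))) {
    f0 <- f0 %||% mean(x[pre])
    if (f0 == 0) abort("Baseline F0 is zero; dF/F undefined.")
    out <- tibble(time = t, dff = (x - f0) / f0)
    class(out) <- c("bq_response_trace", class(out))
    attr(out, "stimulus_onset") <- stimulus_onset
    attr(out, "f0") <- f0
    return(out)
  }
  d <- dim(x)
  if (is.null(f0)) f0 <- apply(x[pre, , , drop = FALSE], c(2, 3), mean)
  if (is.matrix(f0) && !all(dim(f0) == d[2:3])) {
    abort("`f0` matrix does not match the frame size.")
  }
  bad <- f0 == 0
  if (any(bad)) {
    warn(sprintf("%d pixel(s) with zero baseline masked NA.", sum(bad)))
    f0[bad] <- NA_real_
  }
  f0a <- if (is.matrix(f0)) {
    aperm(array(f0, c(d[2], d[3], d[1])), c(3, 1, 2))
  } else {
    f0
  }
  out <- (x - f0a) / f0a
  attr(out, "stimulus_onset") <- stimulus_onset
  attr(out, "f0") <- f0
  out
}

#' Pointwise average across trials
#'
#' @param trials A list of equal-length response traces
#'   (`bq_response_trace` tibbles or numeric vectors) or equal-shape
#'   arrays.
#' @return The pointwise mean, with the class/attributes of the first
#'   element preserved.
#' @export
trial_average <- function(trials) {
  if (!is.list(trials) || length(trials) < 1) {
    abort("`trials` must be a non-empty list.")
  }
  first <- trials[[1]]
  if (inherits(first, "bq_response_trace") || is.data.frame(first)) {
    lens <- vapply(trials, nrow, integer(1))
    if (length(unique(lens)) != 1) abort("Trials have unequal lengths.")
    dff <- rowMeans(vapply(trials, function(tr) tr$dff, numeric(lens[1])))
    out <- first
    out$dff <- dff
    return(out)
  }
  dims <- lapply(trials, function(x) dim(x) %||% length(x))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("Trials have unequal shapes.")
  }
  Reduce(`+`, trials) / length(trials)
}

#' Response metrics of an averaged dF/F trace
#'
#' Computes the standard whisker-evoked response metrics: `peak` (maximum
#' post-stimulus dF/F), `latency` (stimulus to peak, s), `duration` (time
#' from stimulus onset until the first post-peak sample at or below 20% of
#' the peak, s), `auc` (sum of dF/F samples from stimulus onset through
#' the duration endpoint), `auc_norm = auc / peak`, and `auc_time`
#' (`auc` scaled by the sample interval, dF/F x s; exposed but not the
#' default reporting unit). A non-positive peak flags the response
#' `non_responsive`; a response that never returns to 20% of peak is
#' flagged `censored` with `duration` equal to the remaining trial length.
#'
#' @param trace A `bq_response_trace` tibble (or any data frame with
#'   `time` and `dff`).
#' @param stimulus_onset Stimulus time in seconds; defaults to the trace
#'   attribute.
#' @return A one-row tibble of metrics and flags.
#' @export
response_metrics <- function(trace, stimulus_onset = NULL) {
  stimulus_onset <- stimulus_onset %||% attr(trace, "stimulus_onset")
  if (is.null(stimulus_onset)) abort("`stimulus_onset` is required.")
  t <- trace$time
  dff <- trace$dff
  post <- which(t >= stimulus_onset)
  if (length(post) < 1) abort("Trace contains no post-stimulus samples.")
  dt <- mean(diff(t))
  ipk <- post[which.max(dff[post])]
  peak <- dff[ipk]
  if (peak <= 0) {
    return(tibble(peak = peak, latency = NA_real_, duration = NA_real_,
                  auc = NA_real_, auc_norm = NA_real_, auc_time = NA_real_,
                  non_responsive = TRUE, censored = FALSE))
  }
  latency <- t[ipk] - stimulus_onset
  after_peak <- which(t > t[ipk] & dff <= 0.2 * peak)
  if (length(after_peak) > 0) {
    iend <- after_peak[1]
    duration <- t[iend] - stimulus_onset
    censored <- FALSE
  } else {
    iend <- length(t)
    duration <- t[iend] - stimulus_onset
    censored <- TRUE
  }
  win <- post[1]:iend
  auc <- sum(dff[win])
  tibble(peak = peak, latency = latency, duration = duration,
         auc = auc, auc_norm = auc / peak, auc_time = auc * dt,
         non_responsive = FALSE, censored = censored)
}

#' Evoked cortical area from a stimulus-to-peak projection
#'
#' Maximum-projects the dF/F frames between stimulus onset and the peak
#' time, thresholds the projection at its mean plus two standard
#' deviations of pixel intensity, and reports the supra-threshold area in
#' mm^2.
#'
#' @param stack dF/F array `[frame, y, x]` (trial-averaged).
#' @param frame_rate Sampling rate in Hz.
#' @param stimulus_onset,peak_time Window bounds in seconds
#'   (`peak_time >= stimulus_onset`).
#' @param pixel_size_um Pixel edge length in micrometers (30 um binned
#'   pixels by default).
#' @return A list with `area_mm2`, `n_pixels`, `threshold`, and the
#'   projection matrix.
#' @export
active_area <- function(stack, frame_rate, stimulus_onset, peak_time,
                        pixel_size_um = 30) {
  if (peak_time < stimulus_onset) abort("`peak_time` precedes the stimulus.")
  n <- dim(stack)[1]
  t <- (seq_len(n) - 1) / frame_rate
  win <- which(t >= stimulus_onset & t <= peak_time + 1e-9)
  if (length(win) < 1) abort("Empty stimulus-to-peak frame range.")
  proj <- apply(stack[win, , , drop = FALSE], c(2, 3), max)
  thr <- mean(proj, na.rm = TRUE) + 2 * sd(as.numeric(proj), na.rm = TRUE)
  n_px <- sum(proj > thr, na.rm = TRUE)
  list(area_mm2 = n_px * (pixel_size_um / 1000)^2, n_pixels = n_px,
       threshold = thr, projection = proj)
}

#' Full widefield response pipeline
#'
#' Runs the complete imaging chain on a dual-channel trial set: spatial
#' binning, per-pixel detrend and band-pass (offset-preserving),
#' hemodynamic correction (optional, for single-wavelength sessions set
#' `correct = FALSE`), dF/F against the 465 nm pre-stimulus baseline,
#' trial averaging, ROI trace extraction, response metrics and evoked
#' area.
#'
#' @param trialset A `bq_trialset` (see [simulate_widefield_trials()]).
#' @param bin_factor Spatial binning factor.
#' @param roi Logical matrix on the binned grid selecting the response
#'   ROI; `NULL` selects the pixel with the largest trial-averaged
#'   post-stimulus dF/F (ROIs are normally chosen by the experimenter —
#'   pass a mask to reproduce that).
#' @param correct Apply dual-wavelength hemodynamic correction?
#' @param preprocess Apply detrend + band-pass before correction?
#' @param pixel_size_um Binned pixel size in micrometers.
#' @return A list of class `bq_widefield_result`: `trace`
#'   (trial-averaged ROI `bq_response_trace`), `metrics` (one-row tibble,
#'   including `area_mm2`), `avg_stack`, `roi`, and `area` details.
#' @export
widefield_metrics <- function(trialset, bin_factor = 4, roi = NULL,
                              correct = TRUE, preprocess = TRUE,
                              pixel_size_um = 30) {
  if (!inherits(trialset, "bq_trialset")) {
    abort("`trialset` must be a bq_trialset.")
  }
  fr <- trialset$frame_rate
  onset <- trialset$stimulus_onset
  nfr <- length(trialset$time)
  tt <- trialset$time
  pre <- tt < onset & tt >= onset - 0.5
  # Trend fitted on the response-free epochs bracketing the trial (the
  # pre-stimulus baseline and the final 0.5 s): fitting through the
  # evoked transient would regress part of the response out, while
  # fitting the baseline alone would extrapolate wildly across the trial.
  trend_win <- pre | tt >= max(tt) - 0.5 + 1e-9
  dff_trials <- lapply(trialset$trials, function(trial) {
    ch465 <- spatial_bin(trial$ch465, bin_factor)
    if (preprocess) ch465 <- preprocess_stack(ch465, fr, trend_window = trend_win)
    f0 <- apply(ch465[pre, , , drop = FALSE], c(2, 3), mean)
    if (correct) {
      ch405 <- spatial_bin(trial$ch405, bin_factor)
      if (preprocess) ch405 <- preprocess_stack(ch405, fr, trend_window = trend_win)
      corrected <- hemodynamic_correct(ch465, ch405)
      d <- dim(corrected)
      # The ratio-of-means scaling removes the temporal mean of the
      # corrected trace, so dF is measured from the corrected trace's own
      # pre-stimulus baseline and normalized by the 465 nm baseline F0.
      c0 <- apply(corrected[pre, , , drop = FALSE], c(2, 3), mean)
      expand <- function(m) aperm(array(m, c(d[2], d[3], d[1])), c(3, 1, 2))
      (corrected - expand(c0)) / expand(f0)
    } else {
      compute_dff(ch465, fr, onset, f0 = f0)
    }
  })
  avg <- trial_average(dff_trials)
  if (is.null(roi)) {
    post_max <- apply(avg[tt >= onset, , , drop = FALSE], c(2, 3), max)
    roi <- post_max == max(post_max)
  }
  roi_idx <- which(roi)
  trace_vals <- vapply(seq_len(nfr), function(k) {
    mean(avg[k, , ][roi_idx])
  }, numeric(1))
  trace <- tibble(time = tt, dff = trace_vals)
  class(trace) <- c("bq_response_trace", class(trace))
  attr(trace, "stimulus_onset") <- onset
  metrics <- response_metrics(trace, onset)
  area <- if (!metrics$non_responsive) {
    active_area(avg, fr, onset, onset + metrics$latency, pixel_size_um)
  } else {
    list(area_mm2 = NA_real_, n_pixels = NA_integer_,
         threshold = NA_real_, projection = NULL)
  }
  metrics$area_mm2 <- area$area_mm2
  structure(list(trace = trace, metrics = metrics, avg_stack = avg,
                 roi = roi, area = area),
            class = "bq_widefield_result")
}
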