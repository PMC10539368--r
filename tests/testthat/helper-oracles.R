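# Independent brute-force oracles used to check the implementation.

# Block-mean binning by explicit loops.
oracle_block_mean <- function(m, f) {
  h <- nrow(m) %/% f
  w <- ncol(m) %/% f
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      out[i, j] <- mean(m[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
    }
  }
  out
}

# dF/F recomputed sample by sample.
oracle_dff <- function(x, frame_rate, onset, pre_window = 0.5) {
  t <- (seq_along(x) - 1) / frame_rate
  f0 <- mean(x[t < onset & t >= onset - pre_window])
  vapply(x, function(v) (v - f0) / f0, numeric(1))
}

# Layer/column bin means by explicit grouping loops.
oracle_bin_map <- function(map, borders, home) {
  layers <- names(borders)
  res <- list()
  for (li in seq_along(layers)) {
    lo <- if (li == 1) 0 else borders[li - 1]
    rows_in <- map$row > lo & map$row <= borders[li]
    for (comp in c("intracolumnar", "transcolumnar")) {
      intra <- map$col >= home[1] & map$col <= home[2]
      sel <- rows_in & (if (comp == "intracolumnar") intra else !intra)
      res[[paste(layers[li], comp)]] <-
        if (any(sel)) mean(map$amplitude[sel]) else NA_real_
    }
  }
  res
}

# Exact one-sample signed-rank p by enumerating all 2^n sign assignments
# (midranks for ties; zeros must be removed by the caller).
oracle_signed_rank_p <- function(values, mu, alternative) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  if (alternative == "less") {
    mean(v_all <= v_obs)
  } else {
    mean(v_all >= v_obs)
  }
}

# Welch statistic and two-sided p from the textbook formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Binned profile means by explicit loops over mask pixels.
oracle_profile <- function(image, roi, n_bins, axis = "row") {
  idx <- which(roi, arr.ind = TRUE)
  pos_px <- if (axis == "row") idx[, 1] else idx[, 2]
  rng <- range(pos_px)
  pos <- (pos_px - rng[1] + 0.5) / (rng[2] - rng[1] + 1)
  bin <- pmin(floor(pos * n_bins) + 1, n_bins)
  vals <- image[roi]
  vapply(seq_len(n_bins), function(b) {
    v <- vals[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

# Exponential-decay response trace on a regular grid.
make_transient_trace <- function(amp = 1, tau = 0.5, frame_rate = 30,
                                 duration = 2.5, onset = 0.5) {
  t <- seq(0, duration - 1 / frame_rate, by = 1 / frame_rate)
  dff <- ifelse(t >= onset, amp * exp(-(t - onset) / tau), 0)
  tr <- tibble::tibble(time = t, dff = dff)
  class(tr) <- c("bq_response_trace", class(tr))
  attr(tr, "stimulus_onset") <- onset
  tr
}
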