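# Imaging chain: binning, filtering, correction, dF/F, metrics, area.

test_that("spatial_bin reproduces the acquisition geometry and block means", {
  m <- matrix(runif(880 * 800), 880, 800)
  b <- spatial_bin(m, 4)
  expect_equal(dim(b), c(220, 200))
  expect_equal(mean(b), mean(m))  # global mean conserved exactly
  # constant frames stay constant
  expect_true(all(spatial_bin(matrix(7, 16, 16), 4) == 7))
  # 8x8 frame with 0..63 row-major -> top-left 4x4 block mean 13.5
  m8 <- matrix(0:63, 8, 8, byrow = TRUE)
  b8 <- spatial_bin(m8, 4)
  expect_equal(dim(b8), c(2, 2))
  expect_equal(b8[1, 1], 13.5)
  expect_error(spatial_bin(m8, 0), "factor")
})

test_that("spatial_bin matches the brute-force oracle on random inputs", {
  set.seed(101)
  for (i in 1:100) {
    f <- sample(2:5, 1)
    h <- f * sample(1:6, 1)
    w <- f * sample(1:6, 1)
    m <- matrix(rnorm(h * w), h, w)
    expect_equal(spatial_bin(m, f), oracle_block_mean(m, f))
  }
  # trailing rows/cols are cropped
  m <- matrix(rnorm(10 * 11), 10, 11)
  expect_message(b <- spatial_bin(m, 4), "cropping")
  expect_equal(b, oracle_block_mean(m[1:8, 1:8], 4))
})

test_that("preprocessing removes trends and DC and attenuates per |H(f)|^2", {
  fs <- 100
  ramp <- seq(0, 10, length.out = 500)
  out <- preprocess_trace(ramp, fs)
  expect_lt(max(abs(out[50:450])), 1e-6 * diff(range(ramp)))
  const <- rep(5, 500)
  expect_lt(max(abs(preprocess_trace(const, fs))), 1e-8)
  # 20 Hz unit sinusoid through the 10 Hz second-order low-pass applied
  # forward-backward: amplitude = squared single-pass magnitude with
  # bilinear-prewarped cutoff
  t <- (0:999) / fs
  x <- sin(2 * pi * 20 * t)
  y <- preprocess_trace(x, fs)
  mid <- 300:700
  fit <- lm(y[mid] ~ sin(2 * pi * 20 * t[mid]) + cos(2 * pi * 20 * t[mid]) - 1)
  amp <- sqrt(sum(coef(fit)^2))
  ratio4 <- (tan(pi * 20 / fs) / tan(pi * 10 / fs))^4
  expect_equal(amp, 1 / (1 + ratio4), tolerance = 0.02)
  expect_error(preprocess_trace(c(1, 2), fs), "3 samples")
})

test_that("hemodynamic correction removes shared multiplicative artifacts", {
  arr <- array(rnorm(20 * 4 * 4, 100, 5), c(20, 4, 4))
  # identical channels -> exactly zero
  expect_equal(max(abs(hemodynamic_correct(arr, arr))), 0)
  # 405 = k * 465 at hemodynamic-only pixels -> zero; invariant to k
  c1 <- hemodynamic_correct(arr, 0.6 * arr)
  expect_lt(max(abs(c1)), 1e-10)
  h <- 1 + 0.05 * sin(seq(0, 6 * pi, length.out = 20))
  st465 <- array(rep(h, 16) * 100, c(20, 4, 4))
  for (k in c(0.3, 1, 2.7)) {
    ck <- hemodynamic_correct(st465, k * st465)
    expect_lt(max(abs(ck)), 1e-10)
  }
  expect_error(hemodynamic_correct(arr, arr[1:10, , ]), "shape")
})

test_that("dF/F matches its definition and the brute-force oracle", {
  expect_true(all(compute_dff(rep(50, 30), 30, 0.5)$dff == 0))
  x <- c(rep(100, 15), rep(150, 15))
  d <- compute_dff(x, 30, 0.5)
  expect_equal(d$dff[20], 0.5)
  set.seed(202)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    fr <- sample(c(20, 30, 40), 1)
    onset <- 0.5
    x <- runif(n, 50, 150)
    expect_equal(compute_dff(x, fr, onset)$dff, oracle_dff(x, fr, onset))
  }
  # pre-stimulus window has mean zero by construction
  x <- runif(75, 90, 110)
  d <- compute_dff(x, 30, 0.5)
  expect_equal(mean(d$dff[d$time < 0.5]), 0, tolerance = 1e-12)
  expect_error(compute_dff(rep(0, 30), 30, 0.5), "zero")
})

test_that("trial averaging is a pointwise mean with error shrinking in n", {
  tr <- make_transient_trace()
  expect_equal(trial_average(list(tr, tr))$dff, tr$dff)
  neg <- tr; neg$dff <- -tr$dff
  expect_true(all(trial_average(list(tr, neg))$dff == 0))
  set.seed(7)
  noisy <- function(n) {
    lapply(seq_len(n), function(i) {
      x <- tr; x$dff <- tr$dff + rnorm(nrow(tr), 0, 0.3); x
    })
  }
  r60 <- sqrt(mean((trial_average(noisy(60))$dff - tr$dff)^2))
  r5 <- sqrt(mean((trial_average(noisy(5))$dff - tr$dff)^2))
  expect_lt(r60, r5 / 2)  # ~ sqrt(12)-fold expected
  bad <- list(tr, tr[1:10, ])
  expect_error(trial_average(bad), "unequal")
})

test_that("response metrics recover the closed forms of an exponential transient", {
  tr <- make_transient_trace(amp = 1, tau = 0.5, frame_rate = 30)
  m <- response_metrics(tr)
  expect_equal(m$peak, 1)
  expect_equal(m$latency, 0)  # instantaneous rise: peak at onset sample
  expect_lt(abs(m$duration - 0.5 * log(5)), 1 / 30)
  # auc = brute-force sample sum over the duration window; auc_norm = auc
  t <- tr$time
  win <- t >= 0.5 & t <= 0.5 + m$duration + 1e-9
  expect_equal(m$auc, sum(tr$dff[win]))
  expect_equal(m$auc_norm, m$auc)
  expect_equal(m$auc_time, m$auc / 30)
  # never returning to 20% flags censoring
  slow <- make_transient_trace(tau = 10)
  ms <- response_metrics(slow)
  expect_true(ms$censored)
  expect_equal(ms$duration, max(slow$time) - 0.5)
  # flat-negative trace is non-responsive
  flatn <- make_transient_trace(amp = -1)
  expect_true(response_metrics(flatn)$non_responsive)
})

test_that("active area thresholds the stimulus-to-peak projection at mean + 2 SD", {
  flat <- array(1, c(5, 20, 20))
  expect_equal(active_area(flat, 30, 0, 0.1)$area_mm2, 0)
  one <- array(0, c(1, 220, 200))
  one[1, 10, 10] <- 1
  a <- active_area(one, 30, 0, 0, pixel_size_um = 30)
  expect_equal(a$n_pixels, 1)
  expect_equal(a$area_mm2, 9e-4)
  set.seed(303)
  for (i in 1:100) {
    st <- array(rnorm(3 * 12 * 12), c(3, 12, 12))
    res <- active_area(st, 30, 0, 2 / 30)
    proj <- apply(st, c(2, 3), max)
    thr <- mean(proj) + 2 * sd(as.numeric(proj))
    expect_equal(res$n_pixels, sum(proj > thr))
    expect_equal(res$area_mm2, sum(proj > thr) * 0.03^2)
  }
  expect_error(active_area(flat, 30, 1, 0.5), "precedes")
})

test_that("the corrected chain recovers the injected amplitude", {
  spec <- widefield_sim_spec(raw_height = 32, raw_width = 32,
                             response_sigma = 8, n_trials = 20,
                             hemo_amplitude = 0.03, noise_sd = 0.5, seed = 21)
  ts <- simulate_widefield_trials(spec)
  roi <- matrix(FALSE, 8, 8); roi[4:5, 4:5] <- TRUE
  res <- widefield_metrics(ts, roi = roi)
  expect_lt(abs(res$metrics$peak - 0.03) / 0.03, 0.1)
  expect_false(res$metrics$non_responsive)
  expect_true(res$metrics$area_mm2 > 0)
})
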