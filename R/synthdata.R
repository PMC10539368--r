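# Synthetic-data generators. Each simulator emulates the statistical
# structure one analysis module assumes, records the generating parameters
# as a ground-truth attribute, and is a pure function of (spec, seed).

#' Specification for a simulated dual-wavelength widefield session
#'
#' Defaults mirror a typical interleaved dual-LED acquisition: 2.5 s trials
#' with a 0.5 s pre-stimulus period, 30 Hz per channel after de-interleaving
#' (60 Hz camera rate), at least 60 trials, and raw 880 x 800 frames that
#' bin 4 x 4 down to 220 x 200 pixels of ~30 um. Both channels carry the
#' same multiplicative hemodynamic oscillation (scaled by per-channel
#' gains); only the calcium-sensitive 465 nm channel carries the
#' stimulus-locked neural transient (instantaneous rise at stimulus onset,
#' single-exponential decay, Gaussian spatial footprint).
#'
#' @param raw_height,raw_width Raw frame size in pixels before binning.
#' @param frame_rate Frames per second per channel after de-interleaving.
#' @param trial_duration Trial length in seconds.
#' @param pre_stim Pre-stimulus baseline period in seconds.
#' @param n_trials Number of trials.
#' @param neural_amplitude Peak dF/F of the neural transient.
#' @param neural_tau Decay time constant of the transient, seconds.
#' @param response_center `c(y, x)` pixel center of the response footprint;
#'   `NULL` places it at the frame center.
#' @param response_sigma Gaussian footprint SD in pixels.
#' @param hemo_amplitude Fractional amplitude of the shared hemodynamic
#'   oscillation.
#' @param hemo_freq Hemodynamic frequency in Hz (stand-in for heart /
#'   respiration).
#' @param channel_gains Length-2 gains `c(g465, g405)` multiplying baseline
#'   fluorescence per channel.
#' @param noise_sd Additive Gaussian noise SD in fluorescence units.
#' @param baseline Scalar baseline fluorescence F0 used when
#'   `baseline_map` is `NULL`.
#' @param baseline_map Optional per-pixel F0 matrix (`raw_height` x
#'   `raw_width`).
#' @param seed Integer RNG seed.
#' @return A list of class `bq_widefield_spec`.
#' @export
widefield_sim_spec <- function(raw_height = 880, raw_width = 800,
                               frame_rate = 30, trial_duration = 2.5,
                               pre_stim = 0.5, n_trials = 60,
                               neural_amplitude = 0.03, neural_tau = 0.5,
                               response_center = NULL, response_sigma = 60,
                               hemo_amplitude = 0.05, hemo_freq = 1,
                               channel_gains = c(g465 = 1, g405 = 0.6),
                               noise_sd = 2, baseline = 1000,
                               baseline_map = NULL, seed = 1L) {
  check_number(raw_height, "raw_height", 1)
  check_number(raw_width, "raw_width", 1)
  check_number(frame_rate, "frame_rate", 0, strict = TRUE)
  check_number(trial_duration, "trial_duration", 0, strict = TRUE)
  check_number(pre_stim, "pre_stim", 0)
  if (pre_stim >= trial_duration) abort("`pre_stim` must be < `trial_duration`.")
  check_number(n_trials, "n_trials", 1)
  check_number(neural_amplitude, "neural_amplitude", 0)
  check_number(neural_tau, "neural_tau", 0, strict = TRUE)
  check_number(response_sigma, "response_sigma", 0, strict = TRUE)
  check_number(hemo_amplitude, "hemo_amplitude", 0)
  check_number(hemo_freq, "hemo_freq", 0)
  check_number(noise_sd, "noise_sd", 0)
  if (length(channel_gains) != 2 || any(channel_gains <= 0)) {
    abort("`channel_gains` must be two positive gains (g465, g405).")
  }
  if (is.null(response_center)) {
    response_center <- c((raw_height + 1) / 2, (raw_width + 1) / 2)
  }
  structure(
    list(
      raw_height = as.integer(raw_height), raw_width = as.integer(raw_width),
      frame_rate = frame_rate, trial_duration = trial_duration,
      pre_stim = pre_stim, n_trials = as.integer(n_trials),
      neural_amplitude = neural_amplitude, neural_tau = neural_tau,
      response_center = response_center, response_sigma = response_sigma,
      hemo_amplitude = hemo_amplitude, hemo_freq = hemo_freq,
      channel_gains = unname(channel_gains), noise_sd = noise_sd,
      baseline = baseline, baseline_map = baseline_map, seed = as.integer(seed)
    ),
    class = "bq_widefield_spec"
  )
}

#' Simulate a dual-channel widefield trial set
#'
#' Generates `n_trials` paired 465/405 nm frame stacks. The 405 nm channel
#' carries only the shared hemodynamic artifact; the 465 nm channel carries
#' both the artifact and the stimulus-locked neural transient. Channels are
#' produced already de-interleaved at `frame_rate` each, with the
#' half-sample timing offset of interleaved acquisition recorded in the
#' metadata.
#'
#' @param spec A [widefield_sim_spec()].
#' @return An object of class `bq_trialset`: a list with `trials` (each a
#'   list of `ch465` and `ch405` arrays indexed `[frame, y, x]`),
#'   `frame_rate`, `stimulus_onset`, `time`, `channel_offset_s`, and
#'   `pixel_size_um` (raw pixels). Ground truth is attached (see
#'   [ground_truth()]).
#' @export
simulate_widefield_trials <- function(spec = widefield_sim_spec()) {
  if (!inherits(spec, "bq_widefield_spec")) {
    abort("`spec` must come from widefield_sim_spec().")
  }
  n_frames <- round(spec$trial_duration * spec$frame_rate)
  t <- (seq_len(n_frames) - 1) / spec$frame_rate
  f0 <- spec$baseline_map %||%
    matrix(spec$baseline, spec$raw_height, spec$raw_width)
  if (!all(dim(f0) == c(spec$raw_height, spec$raw_width))) {
    abort("`baseline_map` does not match the raw frame size.")
  }
  yy <- seq_len(spec$raw_height)
  xx <- seq_len(spec$raw_width)
  g <- exp(-(outer((yy - spec$response_center[1])^2,
                   (xx - spec$response_center[2])^2, "+")) /
             (2 * spec$response_sigma^2))
  neural_t <- ifelse(t >= spec$pre_stim,
                     spec$neural_amplitude *
                       exp(-(t - spec$pre_stim) / spec$neural_tau), 0)
  g465 <- spec$channel_gains[1]
  g405 <- spec$channel_gains[2]
  offset <- 1 / (2 * spec$frame_rate)
  trials <- with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_trials), function(i) {
      phase <- runif(1, 0, 2 * pi)
      hemo465 <- 1 + spec$hemo_amplitude * sin(2 * pi * spec$hemo_freq * t + phase)
      hemo405 <- 1 + spec$hemo_amplitude *
        sin(2 * pi * spec$hemo_freq * (t + offset) + phase)
      ch465 <- array(0, c(n_frames, spec$raw_height, spec$raw_width))
      ch405 <- array(0, c(n_frames, spec$raw_height, spec$raw_width))
      for (k in seq_len(n_frames)) {
        ch465[k, , ] <- g465 * f0 * hemo465[k] * (1 + neural_t[k] * g)
        ch405[k, , ] <- g405 * f0 * hemo405[k]
      }
      if (spec$noise_sd > 0) {
        ch465 <- ch465 + array(rnorm(length(ch465), 0, spec$noise_sd), dim(ch465))
        ch405 <- ch405 + array(rnorm(length(ch405), 0, spec$noise_sd), dim(ch405))
      }
      list(ch465 = ch465, ch405 = ch405)
    })
  })
  out <- structure(
    list(
      trials = trials, frame_rate = spec$frame_rate,
      stimulus_onset = spec$pre_stim, time = t,
      channel_offset_s = offset, pixel_size_um = 7.5,
      n_trials = spec$n_trials
    ),
    class = "bq_trialset"
  )
  set_ground_truth(out, list(
    neural_amplitude = spec$neural_amplitude, neural_tau = spec$neural_tau,
    response_center = spec$response_center,
    response_sigma = spec$response_sigma,
    hemo_amplitude = spec$hemo_amplitude, hemo_freq = spec$hemo_freq,
    channel_gains = spec$channel_gains, noise_sd = spec$noise_sd,
    seed = spec$seed
  ))
}

#' Specification for a simulated barrel-field section image
#'
#' Emulates a tangential section through the layer-4 barrel field: a 3 x 3
#' grid of circular barrels (center barrel principal, e.g. C2) with labeled
#' cells rendered as Gaussian spots on a smooth background with an optional
#' gradient. Cell counts per barrel are Poisson.
#'
#' @param height,width Image size in pixels.
#' @param barrel_radius Barrel radius in pixels.
#' @param barrel_spacing Center-to-center spacing in pixels.
#' @param cells_inside Expected number of cells in the principal barrel.
#' @param cells_outside Expected number of cells in each surround barrel.
#' @param cell_intensity Peak intensity added per cell.
#' @param psf_sigma Gaussian point-spread SD in pixels for rendered cells.
#' @param background Background level.
#' @param gradient Total left-to-right background gradient amplitude.
#' @param seed Integer RNG seed.
#' @return A list of class `bq_barrel_spec`.
#' @export
barrel_sim_spec <- function(height = 180, width = 180, barrel_radius = 22,
                            barrel_spacing = 60, cells_inside = 100,
                            cells_outside = 50, cell_intensity = 120,
                            psf_sigma = 1.5, background = 20, gradient = 0,
                            seed = 1L) {
  check_number(height, "height", 8)
  check_number(width, "width", 8)
  check_number(barrel_radius, "barrel_radius", 1)
  check_number(cells_inside, "cells_inside", 0)
  check_number(cells_outside, "cells_outside", 0)
  if (barrel_spacing < 2 * barrel_radius) {
    warn("Barrel ROIs overlap (spacing < 2 * radius).")
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         barrel_radius = barrel_radius, barrel_spacing = barrel_spacing,
         cells_inside = cells_inside, cells_outside = cells_outside,
         cell_intensity = cell_intensity, psf_sigma = psf_sigma,
         background = background, gradient = gradient, seed = as.integer(seed)),
    class = "bq_barrel_spec"
  )
}

barrel_layout <- function(spec) {
  cy <- (spec$height + 1) / 2
  cx <- (spec$width + 1) / 2
  s <- spec$barrel_spacing
  grid <- expand.grid(dy = c(-s, 0, s), dx = c(-s, 0, s))
  names_row <- c("B1", "C1", "D1", "B2", "C2", "D2", "B3", "C3", "D3")
  tibble(
    barrel = names_row,
    y = cy + grid$dy, x = cx + grid$dx, r = spec$barrel_radius,
    principal = names_row == "C2"
  )
}

circle_mask <- function(height, width, y0, x0, r) {
  outer(seq_len(height), seq_len(width),
        function(y, x) (y - y0)^2 + (x - x0)^2 <= r^2)
}

#' Simulate a barrel-field image with labeled cells
#'
#' @param spec A [barrel_sim_spec()].
#' @return A list of class `bq_barrel_image` with `image` (matrix),
#'   `cells` (tibble: `x`, `y`, `barrel`, `inside_principal`), `barrels`
#'   (layout tibble) and `rois` (named logical masks, including
#'   `principal` and `surround`). Ground truth is attached.
#' @export
simulate_barrel_image <- function(spec = barrel_sim_spec()) {
  if (!inherits(spec, "bq_barrel_spec")) {
    abort("`spec` must come from barrel_sim_spec().")
  }
  layout <- barrel_layout(spec)
  cells <- with_local_seed(spec$seed, {
    purrr::pmap_dfr(layout, function(barrel, y, x, r, principal) {
      lambda <- if (principal) spec$cells_inside else spec$cells_outside
      n <- rpois(1, lambda)
      if (n == 0) return(tibble())
      rr <- r * sqrt(runif(n))
      th <- runif(n, 0, 2 * pi)
      tibble(x = x + rr * cos(th), y = y + rr * sin(th),
             barrel = barrel, inside_principal = principal)
    })
  })
  img <- matrix(spec$background, spec$height, spec$width) +
    matrix(rep(seq(0, spec$gradient, length.out = spec$width),
               each = spec$height), spec$height, spec$width)
  if (nrow(cells) > 0) {
    half <- ceiling(3 * spec$psf_sigma)
    ker_ax <- seq(-half, half)
    for (i in seq_len(nrow(cells))) {
      yi <- round(cells$y[i]); xi <- round(cells$x[i])
      ys <- yi + ker_ax; xs <- xi + ker_ax
      ok_y <- ys >= 1 & ys <= spec$height
      ok_x <- xs >= 1 & xs <= spec$width
      spot <- spec$cell_intensity *
        exp(-outer(ker_ax[ok_y]^2, ker_ax[ok_x]^2, "+") /
              (2 * spec$psf_sigma^2))
      img[ys[ok_y], xs[ok_x]] <- img[ys[ok_y], xs[ok_x]] + spot
    }
  }
  principal <- layout[layout$principal, ]
  surround <- layout[!layout$principal, ]
  rois <- list(
    principal = circle_mask(spec$height, spec$width,
                            principal$y, principal$x, principal$r),
    surround = Reduce(`|`, purrr::pmap(surround, function(barrel, y, x, r, principal) {
      circle_mask(spec$height, spec$width, y, x, r)
    }))
  )
  out <- structure(
    list(image = img, cells = cells, barrels = layout, rois = rois),
    class = "bq_barrel_image"
  )
  set_ground_truth(out, list(
    cells_inside = spec$cells_inside, cells_outside = spec$cells_outside,
    n_surround = nrow(surround),
    expected_outside_inside_ratio =
      if (spec$cells_inside > 0) {
        nrow(surround) * spec$cells_outside / spec$cells_inside
      } else {
        NA_real_
      },
    background = spec$background, gradient = spec$gradient, seed = spec$seed
  ))
}

#' Simulate per-region presynaptic counts for rabies tracing
#'
#' Draws one Poisson count per brain region with the given expected counts,
#' alongside a starter-neuron count, emulating registered monosynaptic
#' tracing tallies.
#'
#' @param rates Named numeric vector of expected presynaptic counts per
#'   region.
#' @param starter_count Number of starter neurons (>= 1).
#' @param animal Optional animal identifier stored in the table.
#' @param seed Integer RNG seed.
#' @return A tibble (`region`, `count`, `starter_count`, `animal`) with
#'   ground truth attached.
#' @export
simulate_tracing_counts <- function(rates, starter_count, animal = "a1",
                                    seed = 1L) {
  if (is.null(names(rates)) || any(rates < 0)) {
    abort("`rates` must be a named vector of non-negative expected counts.")
  }
  check_number(starter_count, "starter_count", 1)
  counts <- with_local_seed(seed, rpois(length(rates), rates))
  out <- tibble(
    animal = animal, region = names(rates), count = as.integer(counts),
    starter_count = as.integer(starter_count)
  )
  set_ground_truth(out, list(rates = as.list(rates),
                             starter_count = starter_count, seed = seed))
}

#' Simulate a texture-interaction session
#'
#' Generates interaction bouts for a two-texture (familiar vs novel)
#' session. Each valid bout is assigned to the novel texture with
#' probability `p` and given an exponentially distributed duration; a
#' fraction of bouts is marked as non-whisker contacts or excluded
#' (pass-through / climbing) to exercise the filtering rules.
#'
#' @param p Probability that a bout is directed at the novel texture.
#' @param n_bouts Number of bouts.
#' @param mean_bout Mean bout duration in seconds.
#' @param p_contact Probability that a bout carries whisker contact.
#' @param p_excluded Probability that a bout is flagged excluded.
#' @param segment Session segment label (the discrimination index is
#'   computed on the `"test"` segment).
#' @param seed Integer RNG seed.
#' @return A bout tibble (`segment`, `texture`, `start`, `end`, `in_zone`,
#'   `whisker_contact`, `excluded`) with ground truth attached.
#' @export
simulate_behavior_session <- function(p = 0.5, n_bouts = 60, mean_bout = 2,
                                      p_contact = 1, p_excluded = 0,
                                      segment = "test", seed = 1L) {
  if (p < 0 || p > 1) abort("`p` must lie in [0, 1].")
  check_number(n_bouts, "n_bouts", 1)
  check_number(mean_bout, "mean_bout", 0, strict = TRUE)
  out <- with_local_seed(seed, {
    dur <- rexp(n_bouts, 1 / mean_bout)
    gap <- rexp(n_bouts, 1 / 5)
    start <- cumsum(gap) + cumsum(c(0, head(dur, -1)))
    tibble(
      segment = segment,
      texture = ifelse(runif(n_bouts) < p, "novel", "familiar"),
      start = start, end = start + dur,
      in_zone = TRUE,
      whisker_contact = runif(n_bouts) < p_contact,
      excluded = runif(n_bouts) < p_excluded
    )
  })
  set_ground_truth(out, list(p = p, n_bouts = n_bouts, mean_bout = mean_bout,
                             expected_index = 2 * p - 1, seed = seed))
}

#' Simulate animal-clustered categorical morphology data
#'
#' Generates the data-generating process assumed by the random-intercept
#' logistic model: per-animal intercepts are Normal(0, sigma^2) and each
#' neuron's outcome (pyramidal vs spiny stellate) is Bernoulli with
#' logit = baseline + beta * group + intercept_animal.
#'
#' @param n_animals Integer vector of animals per group (length = number of
#'   groups, default two groups).
#' @param neurons_per_animal Neurons scored per animal; scalar or a list
#'   matching `n_animals`.
#' @param beta Fixed group effect on the log-odds scale (second group vs
#'   first).
#' @param sigma Between-animal SD of the random intercept (>= 0).
#' @param baseline Baseline log-odds of the outcome in the reference group.
#' @param groups Group labels.
#' @param seed Integer RNG seed.
#' @return A long tibble (`animal`, `group`, `outcome`) with ground truth
#'   attached. `outcome` is 0/1 (1 = pyramidal).
#' @export
simulate_morphology <- function(n_animals = c(19, 8), neurons_per_animal = 10,
                                beta = 2.41, sigma = 0.38, baseline = qlogis(0.42),
                                groups = c("control", "mutant"), seed = 1L) {
  check_number(sigma, "sigma", 0)
  if (length(n_animals) != length(groups)) {
    abort("`n_animals` must give one count per group.")
  }
  out <- with_local_seed(seed, {
    purrr::map_dfr(seq_along(groups), function(gi) {
      purrr::map_dfr(seq_len(n_animals[gi]), function(ai) {
        n <- if (length(neurons_per_animal) > 1) {
          neurons_per_animal[[gi]]
        } else {
          neurons_per_animal
        }
        u <- rnorm(1, 0, sigma)
        eta <- baseline + beta * (gi - 1) + u
        tibble(
          animal = sprintf("%s_%02d", groups[gi], ai),
          group = groups[gi],
          outcome = rbinom(n, 1, plogis(eta))
        )
      })
    })
  })
  out$group <- factor(out$group, levels = groups)
  set_ground_truth(out, list(beta = beta, sigma = sigma, baseline = baseline,
                             n_animals = n_animals,
                             neurons_per_animal = neurons_per_animal,
                             seed = seed))
}

#' Simulate animal-clustered continuous outcomes
#'
#' Companion generator for the linear mixed model: per-section (or
#' per-replicate) outcomes are `baseline + beta * group + u_animal + e`,
#' with `u ~ N(0, sigma^2)` and `e ~ N(0, tau^2)`.
#'
#' @param n_animals Animals per group.
#' @param sections_per_animal Replicates per animal.
#' @param beta Group effect (difference of means).
#' @param sigma Between-animal SD.
#' @param tau Residual SD.
#' @param baseline Mean of the reference group.
#' @param groups Group labels.
#' @param seed Integer RNG seed.
#' @return A long tibble (`animal`, `group`, `outcome`) with ground truth.
#' @export
simulate_clustered_values <- function(n_animals = c(3, 3),
                                      sections_per_animal = 6,
                                      beta = 21.1, sigma = 3.78, tau = 3,
                                      baseline = 3.1,
                                      groups = c("control", "mutant"),
                                      seed = 1L) {
  check_number(sigma, "sigma", 0)
  check_number(tau, "tau", 0)
  out <- with_local_seed(seed, {
    purrr::map_dfr(seq_along(groups), function(gi) {
      purrr::map_dfr(seq_len(n_animals[gi]), function(ai) {
        u <- rnorm(1, 0, sigma)
        tibble(
          animal = sprintf("%s_%02d", groups[gi], ai),
          group = groups[gi],
          outcome = baseline + beta * (gi - 1) + u +
            rnorm(sections_per_animal, 0, tau)
        )
      })
    })
  })
  out$group <- factor(out$group, levels = groups)
  set_ground_truth(out, list(beta = beta, sigma = sigma, tau = tau,
                             baseline = baseline, seed = seed))
}

#' Simulate a photostimulation mapping recording
#'
#' One post-stimulus current trace per stimulation site on a grid (15 x 28
#' by default). Connected sites receive injected inward-current events
#' (instantaneous rise, exponential decay) at known latencies; all sites
#' receive additive Gaussian noise.
#'
#' @param connections Tibble of injected events with columns `row`, `col`,
#'   `amplitude_pa` (> 0, reported as inward magnitude) and `latency_s`
#'   (relative to the stimulus). Multiple rows per site are allowed.
#' @param n_rows,n_cols Grid dimensions.
#' @param sample_rate Sampling rate in Hz.
#' @param sweep_duration Sweep length in seconds.
#' @param stimulus_time Photostimulus time within the sweep, seconds.
#' @param tau Event decay time constant, seconds.
#' @param noise_sd Noise SD in pA.
#' @param seed Integer RNG seed.
#' @return An object of class `bq_photostim`: `traces` (matrix site x
#'   sample, pA, inward negative), `sites` (tibble `site`, `row`, `col`),
#'   `sample_rate`, `stimulus_time`, `sweep_duration`. Ground truth holds
#'   the injected connection map.
#' @export
simulate_epsc_grid <- function(connections = NULL, n_rows = 15, n_cols = 28,
                               sample_rate = 5000, sweep_duration = 0.35,
                               stimulus_time = 0.05, tau = 0.01,
                               noise_sd = 0, seed = 1L) {
  check_number(n_rows, "n_rows", 1)
  check_number(n_cols, "n_cols", 1)
  check_number(sample_rate, "sample_rate", 0, strict = TRUE)
  if (is.null(connections)) {
    connections <- tibble(row = integer(), col = integer(),
                          amplitude_pa = numeric(), latency_s = numeric())
  }
  if (nrow(connections) > 0 &&
      (any(connections$row < 1 | connections$row > n_rows) ||
       any(connections$col < 1 | connections$col > n_cols))) {
    abort("`connections` reference sites outside the grid.")
  }
  n_samples <- round(sweep_duration * sample_rate)
  t <- (seq_len(n_samples) - 1) / sample_rate
  n_sites <- n_rows * n_cols
  sites <- tibble(
    site = seq_len(n_sites),
    row = rep(seq_len(n_rows), each = n_cols),
    col = rep(seq_len(n_cols), times = n_rows)
  )
  traces <- matrix(0, n_sites, n_samples)
  if (nrow(connections) > 0) {
    for (i in seq_len(nrow(connections))) {
      s <- (connections$row[i] - 1) * n_cols + connections$col[i]
      t0 <- stimulus_time + connections$latency_s[i]
      on <- t >= t0 - 1e-9
      traces[s, on] <- traces[s, on] -
        connections$amplitude_pa[i] * exp(-(t[on] - t0) / tau)
    }
  }
  if (noise_sd > 0) {
    traces <- traces + with_local_seed(seed, {
      matrix(rnorm(length(traces), 0, noise_sd), n_sites, n_samples)
    })
  }
  out <- structure(
    list(traces = traces, sites = sites, sample_rate = sample_rate,
         stimulus_time = stimulus_time, sweep_duration = sweep_duration,
         n_rows = n_rows, n_cols = n_cols),
    class = "bq_photostim"
  )
  set_ground_truth(out, list(
    connections = as.data.frame(connections), tau = tau,
    noise_sd = noise_sd, seed = seed
  ))
}
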