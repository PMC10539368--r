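---
title: "barrelquant: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{barrelquant: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelquant)
```

barrelquant quantifies barrel-cortex experiments of five kinds: widefield
calcium-imaging responses with dual-wavelength hemodynamic correction,
intensity profiling of ISH/c-fos section images, monosynaptic
rabies-tracing connectivity, laser-photostimulation input maps, and a
novel-texture-discrimination behavioral index — plus the mixed-model and
bootstrap statistics appropriate for animal-clustered outcomes. A
simulation module generates each input type with known ground truth, so
every pipeline is validated end to end against parameters it should
recover. This vignette explains the underlying models, the tunable
parameters, and the numerical decisions that were genuinely open.

## Widefield imaging chain

The measurement model is standard for single-photon widefield GCaMP
imaging. The camera interleaves two LEDs at 60 Hz, giving two 30 Hz
channels after de-interleaving: a calcium-sensitive channel (465 nm) and
a calcium-insensitive isosbestic channel (405 nm). Fluorescence at pixel
$(y,x)$ is modeled as

$$F_{465}(t) = g_{465}\,F_0\,(1 + h(t))\,(1 + n(t)), \qquad
  F_{405}(t) = g_{405}\,F_0\,(1 + h(t)),$$

where $h(t)$ is a shared multiplicative hemodynamic fluctuation (blood
volume/oxygenation changes absorb both excitation and emission light)
and $n(t)$ is the neural ΔF/F. Trials last 2.5 s with a 0.5 s
pre-stimulus baseline; pixels are binned 4 × 4 to ~30 µm.

The chain is: `spatial_bin()` (block mean), per-pixel detrend +
band-pass (`preprocess_trace()` / the stack equivalent: second-order
Butterworth, 0.01 Hz high-pass and 10 Hz low-pass, both applied
zero-phase so latencies are unbiased), `hemodynamic_correct()`
(`corrected = F465 − s·F405` with $s$ the per-pixel ratio of temporal
means — this direction preserves positive stimulus responses),
ΔF/F against the 465 nm pre-stimulus baseline, `trial_average()`,
`response_metrics()` and `active_area()`.

Numerical choices worth knowing:

* **Trend window.** A least-squares line fitted through the whole trial
  regresses part of the evoked transient out (it biases the response
  tail upward by enough to censor the duration metric), while a line
  fitted to the 0.5 s baseline alone extrapolates any ~1 Hz
  hemodynamic oscillation wildly across the trial. `widefield_metrics()`
  therefore fits the trend on the response-free epochs bracketing the
  trial (baseline plus the final 0.5 s) and both channels are treated
  identically so the correction still cancels shared structure. The
  exported `preprocess_trace()` defaults to the whole-series fit and
  takes a `trend_window` argument.
* **Baseline of the corrected trace.** Because the scale factor is a
  ratio of temporal means, the corrected trace has zero temporal mean by
  construction; ΔF is measured from the corrected trace's own
  pre-stimulus mean and normalized by the 465 nm baseline $F_0$.
* **Channel pairing.** The half-sample timing offset between interleaved
  channels is recorded in the metadata but correction pairs
  nearest samples without interpolation; the residual is a small
  (≈ $2\sin(\pi f_h/f_s)$-scaled) ripple that trial averaging shrinks.
* **Metrics.** Peak is the maximum post-stimulus ΔF/F; latency the time
  from stimulus to peak; duration runs from stimulus onset to the first
  post-peak sample at or below 20 % of peak (first crossing wins;
  traces that never return are flagged `censored`); AUC is a plain
  sample sum over the duration window (a `auc_time` variant scaled by
  the sample interval is also returned), normalized AUC is AUC/peak.
  The evoked area thresholds the stimulus-to-peak maximum projection at
  its mean + 2 SD (the "2 SD" rule is read as centered on the
  projection mean) and multiplies the supra-threshold pixel count by
  the pixel area.
* **ROIs are inputs.** Response ROIs are chosen by the experimenter in
  practice; `widefield_metrics(roi = NULL)` falls back to the pixel
  with the largest trial-averaged post-stimulus ΔF/F, which is
  convenient but subject to selection bias at low SNR.
* Single-wavelength sessions skip the correction via `correct = FALSE`.

## Section-image profiling

`subtract_background()` implements rolling-ball background estimation as
a grayscale opening with a spherical (non-flat) structuring element —
the surface an ideal ball of the given radius reaches when rolled under
the intensity landscape (compiled code; radius 300 px for
cortical-depth profiles, 50 px for c-fos sections). ImageJ additionally
shrinks large images before rolling, so agreement with it is close but
not bit-exact.

`depth_profile_log2fc()` bins mean intensity along the cortical-depth
axis into 10 equal bins and reports per-bin log2(test/control);
`iue_l4_log2fc()` uses a 100-bin radial profile and compares the mean
over the L4 band between the electroporated and contralateral
hemispheres. Profiles are invariant to global intensity rescaling after
normalization, and log2 fold-changes are antisymmetric in their
arguments; bins with zero control intensity are flagged undefined
rather than silently dropped. Registration (centering the principal
barrel, common crop) consumes user-provided landmarks; there is no
automatic registration or barrel segmentation.

`fos_row_profile()` bins a B2–C2–D2 row profile (30 bins by default —
the historical bin count is not fixed, so it is a parameter) and
normalizes to the mean intensity over the principal-barrel (C2)
interval. `fos_ratios()` counts labeled cells outside versus inside the
principal barrel (cell coordinates are inputs, mirroring manual
counting) and, when an image is given, forms the analogous ratio of raw
ROI mean intensities. `group_heatmap()` averages per-image Otsu-binarized
masks; "automatic threshold" is read as Otsu's criterion, computed on a
256-level histogram.

`directional_shift_test()` is a one-sample Wilcoxon signed-rank test of
per-gene mean log fold-changes against a shifted null (±0.1 by
default), one-sided in the stated direction. The legend language that
motivated it names a rank-sum test with a one-sample shift null; since
a two-sample rank-sum statistic has no null of that form, the
one-sample signed-rank reading is implemented. For n ≤ 12 the exact
null is computed by convolving the per-rank sign distribution — using
midranks, so fully tied inputs (e.g. nine identical strong decreases,
p = 1/2⁹) stay exact; `wilcox.test`'s exact path covers 13–25 without
ties, and the normal approximation is used beyond. Correction across a
gene-family (Holm) is left to the caller via `p.adjust()`.

## Connectivity indices

`compute_ioc()` normalizes per-region presynaptic counts by the number
of starter neurons (IOC), per animal and per hemisphere (pooling is a
caller decision); `ioc_ratio()` forms region ratios such as VPM/POm.
Counts are assumed to already exclude starter neurons from their own
region. `double_label_percent()` reports per-section percentages of
double-labeled neurons among transfected neurons, plus labeling density
when ROI areas are given. Atlas registration is upstream of all of
this: regions are opaque identifiers.

## Photostimulation input maps

`detect_epsc_events()` finds inward-current events as local extrema of
the baseline-subtracted trace exceeding a threshold (default 3 × the
pre-stimulus SD; 1 pA for noise-free traces) whose onsets fall within
150 ms after the stimulus, with an early-latency veto window (default
7 ms) to exclude direct somatic responses, and 5 ms minimum peak
separation. `build_input_map()` sums detected peak amplitudes per
stimulation site on the 15 × 28 grid — invariant to acquisition order —
and `bin_input_map()` averages sites per cortical layer, separately for
the recorded cell's home column (intracolumnar) and the rest
(transcolumnar). Laminar borders and column bounds are inputs in
grid-row units.

## Behavior

`interaction_times()` sums bout durations that qualify as interactions:
inside the 4 cm × 4 cm panel zone, whisker-directed contact, not
excluded (pass-throughs, climbing); overlapping bouts are merged first.
`ntd_index()` is `(novel − familiar) / total` interaction time, in
[−1, 1]; it is antisymmetric under texture-label swap and invariant to
rescaling all durations. The index is computed on the test segment; the
same-texture pre-test is scored but never pooled into it.

## Mixed models and the parametric bootstrap

Categorical morphology data (pyramidal vs spiny stellate, scored per
neuron within animals) call for a random-intercept logistic model:

$$y_{ij} \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}(\beta_0 +
\beta\,\mathrm{group}_i + u_i)\right), \quad u_i \sim N(0, \sigma^2).$$

`fit_binomial_glmm()` maximizes the exact marginal likelihood with
adaptive Gauss–Hermite quadrature: per animal, the integrand is
recentered at its posterior mode (Newton steps) and scaled by the local
curvature before applying the quadrature rule (25 nodes by default; the
estimate is stable to doubling the node count to ~1e-4). σ is optimized
on the log scale with a floor at 1e-6; a fit at the floor is flagged as
a boundary fit, where the model coincides with ordinary logistic
regression and β equals the pooled log-odds ratio
(`pooled_log_odds()`, which applies a +0.5 continuity correction to
degenerate pooled proportions). Standard errors come from the observed
information of the fixed effects with the variance held at its MLE, as
in lme4. `fit_linear_mixed()` is the Gaussian analogue, with the fixed
effects profiled out by closed-form GLS (cluster weight
$n_i/(\tau^2 + n_i\sigma^2)$) so only the two variance parameters are
optimized numerically.

`parametric_bootstrap_test()` tests the group effect by a
likelihood-ratio parametric bootstrap: B datasets are simulated from the
fitted null (random intercepts redrawn), both models are refit to each,
and $p = (1 + \#\{LR^* \ge LR_{obs}\})/(B + 1)$, so p is never zero and
has granularity 1/(B+1) — the default B = 4999 for the logistic model
and 999 for the linear model put the attainable floors at 0.0002 and
0.001. Replicates that fail to refit are dropped and counted. A caveat
worth stating: with very few clusters (e.g. 3 animals per group) the
null model's random intercept can absorb almost any group separation,
which caps the attainable likelihood ratio; bootstrap p-values in such
designs bottom out above the nominal floor no matter how separated the
groups are.

`welch_holm()` wraps two-sided Welch t tests (Satterthwaite degrees of
freedom) with Holm or Benjamini–Hochberg correction across a stated
family — per-layer comparisons, or all pairwise group contrasts.

## The synthetic-data generators

Each generator draws from the statistical model its analysis assumes and
attaches the generating parameters (`ground_truth()`), which round-trip
through a JSON sidecar. Defaults reflect the acquisition they emulate:
2.5 s widefield trials, 0.5 s pre-stimulus, 30 Hz per channel, ≥ 60
trials, raw 880 × 800 frames, hemodynamic oscillation at 1 Hz with 5 %
fractional amplitude, neural transients with instantaneous rise and
single-exponential decay (τ = 0.5 s, amplitude 0.03 ΔF/F) — the step +
exponential shape is chosen deliberately so every response metric has a
closed form to test against. The barrel-field image generator renders
Poisson-placed cells as Gaussian spots on a 3 × 3 barrel grid;
tracing counts are Poisson; bouts are exponential with a Bernoulli
texture choice (expected index 2p − 1); morphology and per-section
outcomes follow the mixed models above; photostimulation traces carry
injected exponential-decay events plus Gaussian noise.

What the generators do **not** emulate — and hence what green tests do
not establish about real data: optics and point-spread realism, vascular
anatomy (hemodynamics here are spatially uniform per frame),
photobleaching (the detrend stage is exercised only against synthetic
trends), motion, non-exponential calcium indicator kinetics, spiking
network dynamics, correlated overdispersion beyond a single random
intercept, and tracker errors in behavioral scoring.

Validation problem sizes are deliberately modest: the widefield recovery
studies use 48–64 px raw frames (keeping the footprint-to-bin geometry
of the full-size default) with the full temporal structure and 60
trials over 10 seeds; bootstrap calibration uses 200 null simulations
at B = 199 with 6 animals per group and 9-node quadrature. These are the
package's own validation choices; all defaults users see remain the
full-scale ones.

## Known limitations

* Rolling-ball backgrounds are exact openings; for radii approaching
  the image size the cost grows as the ball area and ImageJ's
  shrink-based approximation will differ slightly.
* The GLMM supports a single cluster level and a cluster-level binary
  covariate — no crossed effects, random slopes, or REML.
* ML variance components are biased low at small cluster counts; the
  fixed effect is the well-identified quantity.
* Event detection is template-free; heavily overlapping EPSCs within
  the minimum-separation window merge into one event.
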