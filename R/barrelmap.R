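# Section-image quantification: rolling-ball background subtraction,
# binned intensity profiles and log2 fold-changes, c-fos row profiles and
# ratios, directional shift tests, and group heatmaps.

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' spherical structuring element of the given radius (the surface an ideal
#' ball can reach when rolled beneath the intensity landscape) and
#' subtracts it. The result is clamped at zero. ImageJ's implementation
#' additionally shrinks large images before rolling; this version rolls at
#' full resolution, so agreement with ImageJ is close but not bit-exact.
#'
#' @param image Numeric intensity matrix (signal-positive; invert
#'   chromogenic ISH images first).
#' @param radius Ball radius in pixels (>= 1); typical values are 300 for
#'   cortical-depth profiles and 50 for c-fos sections.
#' @return Background-subtracted matrix (>= 0) with the background
#'   estimate attached as attribute `"background"`.
#' @export
subtract_background <- function(image, radius) {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix.")
  }
  check_number(radius, "radius", 1)
  if (radius >= min(dim(image))) {
    abort("`radius` must be smaller than the smallest image dimension.")
  }
  bg <- ball_opening(image, radius)
  out <- pmax(image - bg, 0)
  attr(out, "background") <- bg
  out
}

# Per-bin mean intensity along one image axis, restricted to a mask.
# Positions are normalized to [0, 1] across the ROI extent along the axis.
intensity_profile <- function(image, roi = NULL, n_bins = 10,
                              axis = c("row", "col")) {
  axis <- match.arg(axis)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  if (!identical(dim(roi), dim(image))) {
    abort("`roi` mask must match the image dimensions.")
  }
  idx <- which(roi, arr.ind = TRUE)
  pos_px <- if (axis == "row") idx[, 1] else idx[, 2]
  rng <- range(pos_px)
  pos <- (pos_px - rng[1] + 0.5) / (rng[2] - rng[1] + 1)
  bin <- pmin(floor(pos * n_bins) + 1, n_bins)
  vals <- image[roi]
  means <- vapply(seq_len(n_bins), function(b) {
    v <- vals[bin == b]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  tibble(bin = seq_len(n_bins),
         position = (seq_len(n_bins) - 0.5) / n_bins,
         mean = means)
}

#' Cortical-depth expression profile and per-bin log2 fold-change
#'
#' Bins the mean intensity of a test and a control section along the
#' cortical-depth axis (10 equal bins by default) and reports the per-bin
#' `log2(test / control)`. Bins with zero control intensity are flagged
#' undefined (`NA` with `undefined = TRUE`).
#'
#' @param test,control Intensity matrices sharing ROI geometry.
#' @param roi Optional logical mask (applied to both images).
#' @param n_bins Number of depth bins.
#' @param axis Image axis running pia-to-white-matter (`"row"` default).
#' @return A tibble of class `bq_profile` with `bin`, `position`,
#'   `mean_test`, `mean_control`, `log2fc`, `undefined`.
#' @export
depth_profile_log2fc <- function(test, control, roi = NULL, n_bins = 10,
                                 axis = c("row", "col")) {
  axis <- match.arg(axis)
  if (!identical(dim(test), dim(control))) {
    abort("`test` and `control` must share dimensions.")
  }
  pt <- intensity_profile(test, roi, n_bins, axis)
  pc <- intensity_profile(control, roi, n_bins, axis)
  undef <- is.na(pc$mean) | pc$mean == 0
  l2 <- ifelse(undef, NA_real_, log2(pt$mean / pc$mean))
  out <- tibble(bin = pt$bin, position = pt$position,
                mean_test = pt$mean, mean_control = pc$mean,
                log2fc = l2, undefined = undef)
  class(out) <- c("bq_profile", class(out))
  out
}

#' L4 log2 fold-change between electroporated and contralateral cortex
#'
#' Bins each hemisphere's intensity along the radial (depth) axis into
#' `n_bins` bins (100 by default), averages the bins falling inside the
#' L4 band, and returns `log2(IUE / contralateral)`.
#'
#' @param iue,contra Intensity matrices for the electroporated and
#'   contralateral hemispheres.
#' @param l4_band Normalized `c(lower, upper)` depth interval of L4 on the
#'   binned axis (0 = pia).
#' @param roi Optional logical mask for each image (a list of two masks
#'   or one shared mask).
#' @param n_bins Number of radial bins.
#' @param axis Depth axis.
#' @return A one-row tibble with `log2fc`, `mean_iue`, `mean_contra`.
#' @export
iue_l4_log2fc <- function(iue, contra, l4_band = c(0.35, 0.55), roi = NULL,
                          n_bins = 100, axis = c("row", "col")) {
  axis <- match.arg(axis)
  if (length(l4_band) != 2 || l4_band[1] >= l4_band[2]) {
    abort("`l4_band` must be an increasing (lower, upper) pair.")
  }
  rois <- if (is.list(roi)) roi else list(roi, roi)
  p1 <- intensity_profile(iue, rois[[1]], n_bins, axis)
  p2 <- intensity_profile(contra, rois[[2]], n_bins, axis)
  in_band <- p1$position >= l4_band[1] & p1$position <= l4_band[2]
  if (!any(in_band)) abort("`l4_band` covers no bins.")
  m1 <- mean(p1$mean[in_band], na.rm = TRUE)
  m2 <- mean(p2$mean[in_band], na.rm = TRUE)
  if (!is.finite(m2) || m2 == 0) {
    abort("Contralateral L4 mean intensity is zero; log2FC undefined.")
  }
  tibble(log2fc = log2(m1 / m2), mean_iue = m1, mean_contra = m2)
}

#' One-sided Wilcoxon signed-rank test against a shifted null
#'
#' Tests per-gene mean log fold-changes against a +/- `shift` null: for
#' `direction = "down"` the alternative is that values lie below
#' `-shift`; for `"up"`, above `+shift`. The exact signed-rank null
#' distribution is used for n <= 25 (no ties/zeros), matching full
#' enumeration of the 2^n sign assignments. Correction across the
#' hollow/septa family is left to the caller (e.g.
#' `p.adjust(..., "holm")`).
#'
#' @param values Numeric vector (>= 3 values).
#' @param direction `"down"` or `"up"`.
#' @param shift Null shift magnitude (0.1 by default).
#' @return A one-row tibble with `p_value`, `statistic` (V), `n`,
#'   `direction`, `shift`.
#' @export
directional_shift_test <- function(values, direction = c("down", "up"),
                                   shift = 0.1) {
  direction <- match.arg(direction)
  values <- values[is.finite(values)]
  if (length(values) < 3) abort("Need at least 3 finite values.")
  mu <- if (direction == "down") -shift else shift
  if (all(values == mu)) {
    warn("All values equal the shifted null; p = 1.")
    return(tibble(p_value = 1, statistic = NA_real_,
                  n = length(values), direction = direction, shift = shift))
  }
  alt <- if (direction == "down") "less" else "greater"
  d <- (values - mu)[values != mu]
  if (length(d) < length(values)) {
    warn("Values equal to the shifted null dropped (signed-rank zeros).")
  }
  v_stat <- sum(rank(abs(d))[d > 0])
  p <- if (length(d) <= 12) {
    # exact null by convolving the per-rank sign distribution
    # (midranks handle ties; doubled so rank sums stay integer)
    signed_rank_exact_p(d, alt)
  } else {
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    wt <- suppressWarnings(
      wilcox.test(d, mu = 0, alternative = alt, exact = exact)
    )
    wt$p.value
  }
  tibble(p_value = p, statistic = v_stat,
         n = length(values), direction = direction, shift = shift)
}

signed_rank_exact_p <- function(d, alternative) {
  r2 <- round(2 * rank(abs(d)))
  v2 <- sum(r2[d > 0])
  total <- sum(r2)
  cnt <- numeric(total + 1)
  cnt[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), cnt[seq_len(total + 1 - r)])
    cnt <- cnt + shifted
  }
  probs <- cnt / 2^length(r2)
  if (alternative == "less") {
    sum(probs[seq_len(v2 + 1)])
  } else {
    sum(probs[(v2 + 1):(total + 1)])
  }
}

#' Barrel-row c-fos intensity profile normalized to the principal barrel
#'
#' Bins pixel intensities along the barrel-row axis spanning the
#' B2-C2-D2 barrels and divides by the mean intensity over the principal
#' (C2) interval.
#'
#' @param image Intensity matrix (background-subtracted).
#' @param roi Logical mask of the B2-C2-D2 band; `NULL` uses the whole
#'   image.
#' @param c2_interval Normalized `c(lower, upper)` interval of the C2
#'   barrel along the profile axis.
#' @param n_bins Number of profile bins (30 by default; the bin count of
#'   the original analysis is not fixed, so it is configurable).
#' @param axis Profile axis (`"col"`: across the row of barrels).
#' @return A tibble of class `bq_profile` with `bin`, `position`,
#'   `mean` (raw), and `norm` (C2-normalized).
#' @export
fos_row_profile <- function(image, roi = NULL, c2_interval = c(1 / 3, 2 / 3),
                            n_bins = 30, axis = c("col", "row")) {
  axis <- match.arg(axis)
  p <- intensity_profile(image, roi, n_bins, axis)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  idx <- which(roi, arr.ind = TRUE)
  pos_px <- if (axis == "row") idx[, 1] else idx[, 2]
  rng <- range(pos_px)
  pos <- (pos_px - rng[1] + 0.5) / (rng[2] - rng[1] + 1)
  in_c2 <- pos >= c2_interval[1] & pos <= c2_interval[2]
  c2_mean <- mean(image[roi][in_c2])
  if (!is.finite(c2_mean) || c2_mean == 0) {
    abort("Mean intensity over the C2 interval is zero.")
  }
  out <- tibble(bin = p$bin, position = p$position, mean = p$mean,
                norm = p$mean / c2_mean)
  class(out) <- c("bq_profile", class(out))
  attr(out, "c2_mean") <- c2_mean
  out
}

#' Surround-versus-principal c-fos ratios
#'
#' Computes the ratio of fos-positive cells counted outside versus inside
#' the principal barrel and, when an image is supplied, the analogous
#' ratio of mean expression intensity.
#'
#' @param cells Tibble of cell coordinates (`x`, `y`).
#' @param principal,surround Logical ROI masks (must be disjoint).
#' @param image Optional intensity matrix for the intensity ratio.
#' @return A one-row tibble with `n_inside`, `n_outside`, `count_ratio`,
#'   `intensity_ratio`, and an `undefined` flag.
#' @export
fos_ratios <- function(cells, principal, surround, image = NULL) {
  if (any(principal & surround)) abort("ROIs must be disjoint.")
  locate <- function(mask) {
    xi <- pmin(pmax(round(cells$x), 1), ncol(mask))
    yi <- pmin(pmax(round(cells$y), 1), nrow(mask))
    sum(mask[cbind(yi, xi)])
  }
  n_in <- if (nrow(cells)) locate(principal) else 0L
  n_out <- if (nrow(cells)) locate(surround) else 0L
  undefined <- n_in == 0
  if (undefined) warn("No cells inside the principal barrel; ratio undefined.")
  int_ratio <- NA_real_
  if (!is.null(image)) {
    mi <- mean(image[principal])
    int_ratio <- if (mi == 0) NA_real_ else mean(image[surround]) / mi
  }
  tibble(n_inside = n_in, n_outside = n_out,
         count_ratio = if (undefined) NA_real_ else n_out / n_in,
         intensity_ratio = int_ratio, undefined = undefined)
}

# Otsu's threshold on a 256-bin histogram (maximizes between-class
# variance). Returns a value in the image's intensity range.
otsu_threshold <- function(image, n_levels = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_levels + 1)
  counts <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_levels)
  p <- counts / sum(counts)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_levels]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Group heatmap of automatically thresholded images
#'
#' Binarizes each co-registered image at its Otsu threshold and returns
#' the pixelwise mean of the binary masks (values in `[0, 1]`: the
#' fraction of animals with signal at each location).
#'
#' @param images A non-empty list of co-registered intensity matrices of
#'   identical size.
#' @return A matrix in `[0, 1]`.
#' @export
group_heatmap <- function(images) {
  if (!is.list(images) || length(images) < 1) {
    abort("`images` must be a non-empty list.")
  }
  dims <- lapply(images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("Images must share dimensions.")
  }
  bins <- lapply(images, function(im) (im > otsu_threshold(im)) * 1)
  Reduce(`+`, bins) / length(bins)
}
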