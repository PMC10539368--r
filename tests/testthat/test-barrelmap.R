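# Section-image quantification: background, profiles, shift tests,
# fos ratios, heatmaps.

test_that("rolling-ball background subtraction behaves like a rolling ball", {
  const <- matrix(13, 40, 40)
  expect_true(all(subtract_background(const, 10) == 0))
  # single bright pixel: value preserved minus the background level
  img <- matrix(20, 50, 50)
  img[25, 25] <- 140
  sb <- subtract_background(img, 12)
  expect_equal(sb[25, 25], 120, tolerance = 0.5)
  expect_lt(max(sb[1:10, 1:10]), 1e-9)
  # blobs on a smooth gradient: gradient crushed, blob peaks preserved
  grad <- matrix(rep(seq(0, 30, length.out = 60), each = 60), 60, 60)
  blob <- function(y0, x0, a, s = 2) {
    a * exp(-(outer((1:60 - y0)^2, (1:60 - x0)^2, "+")) / (2 * s^2))
  }
  img2 <- 10 + grad + blob(20, 20, 100) + blob(40, 45, 80)
  sb2 <- subtract_background(img2, 15)
  resid_range <- diff(range(sb2[abs(row(sb2) - 20) > 8 & abs(row(sb2) - 40) > 8]))
  expect_lt(resid_range, diff(range(grad)) / 10)
  expect_gt(sb2[20, 20], 0.9 * 100)
  expect_error(subtract_background(img2, 60), "smaller")
})

test_that("depth profiles and log2 fold-changes match their identities", {
  a <- matrix(runif(900, 1, 3), 30, 30)
  p_same <- depth_profile_log2fc(a, a)
  expect_true(all(p_same$log2fc == 0))
  p_half <- depth_profile_log2fc(a / 2, a)
  expect_equal(p_half$log2fc, rep(-1, 10))
  # piecewise synthetic profile matches brute-force bin means
  img <- matrix(rep(rep(c(1, 5, 2, 8, 3), each = 6), 30), 30, 30)
  ctl <- matrix(runif(900, 2, 4), 30, 30)
  p <- depth_profile_log2fc(img, ctl, n_bins = 10)
  full <- matrix(TRUE, 30, 30)
  expect_equal(p$mean_test, oracle_profile(img, full, 10))
  expect_equal(p$mean_control, oracle_profile(ctl, full, 10))
  expect_equal(p$log2fc, log2(p$mean_test / p$mean_control))
  # antisymmetry
  p_rev <- depth_profile_log2fc(ctl, img, n_bins = 10)
  expect_equal(p$log2fc, -p_rev$log2fc)
  # invariance to global rescaling of both images
  p_scaled <- depth_profile_log2fc(3 * img, 3 * ctl, n_bins = 10)
  expect_equal(p_scaled$log2fc, p$log2fc)
  # zero control bin flagged undefined
  z <- matrix(1, 20, 20); z[1:2, ] <- 0
  pz <- depth_profile_log2fc(a[1:20, 1:20], z)
  expect_true(pz$undefined[1])
  expect_true(is.na(pz$log2fc[1]))
})

test_that("IUE-vs-contralateral L4 log2FC reads off band amplitudes", {
  base <- matrix(2, 100, 40)
  expect_equal(iue_l4_log2fc(base, base, c(0.35, 0.55))$log2fc, 0)
  iue <- base
  iue[36:55, ] <- 8  # 4x the contralateral level in L4 only
  expect_equal(iue_l4_log2fc(iue, base, c(0.355, 0.545))$log2fc, 2)
  a1 <- base; a1[36:55, ] <- 5
  a2 <- base; a2[36:55, ] <- 3
  got <- iue_l4_log2fc(a1, a2, c(0.355, 0.545))
  expect_equal(got$log2fc, log2(5 / 3))
  expect_error(iue_l4_log2fc(base, 0 * base, c(0.35, 0.55)), "zero")
})

test_that("directional shift test equals full sign-assignment enumeration", {
  # nine identical strong decreases: p = 1/2^9
  v <- rep(-1, 9)
  expect_equal(directional_shift_test(v, "down")$p_value, 1 / 512)
  # symmetric around the shifted null -> p ~ 0.5
  v2 <- -0.1 + c(-0.4, -0.3, -0.2, -0.1, 0.1, 0.2, 0.3, 0.4, 1e-3)
  expect_lt(abs(directional_shift_test(v2, "down")$p_value - 0.5), 0.2)
  # matches the independent 2^n enumeration for n <= 12, both directions
  set.seed(404)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    vals <- rnorm(n, -0.2, 0.3)
    expect_equal(directional_shift_test(vals, "down")$p_value,
                 oracle_signed_rank_p(vals, -0.1, "less"))
    expect_equal(directional_shift_test(vals, "up")$p_value,
                 oracle_signed_rank_p(vals, 0.1, "greater"))
  }
  # with ties (midranks enter the enumeration)
  vt <- c(-0.5, -0.5, -0.3, -0.3, 0.2, -0.6, -0.1 + 0.4, -0.8)
  expect_equal(directional_shift_test(vt, "down")$p_value,
               oracle_signed_rank_p(vt, -0.1, "less"))
  expect_warning(out <- directional_shift_test(rep(-0.1, 5), "down"), "null")
  expect_equal(out$p_value, 1)
})

test_that("fos row profiles normalize to the principal-barrel interval", {
  u <- matrix(4, 30, 90)
  p <- fos_row_profile(u, n_bins = 30)
  expect_equal(p$norm, rep(1, 30))
  img <- matrix(1, 30, 90)
  img[, 31:60] <- 2  # C2 twice the surround
  p2 <- fos_row_profile(img, c2_interval = c(1 / 3, 2 / 3), n_bins = 30)
  expect_equal(p2$norm[1:10], rep(0.5, 10))
  expect_equal(p2$norm[12:19], rep(1, 8))
  # synthetic triple-Gaussian row vs brute-force binning
  x <- 1:90
  row_prof <- 1 + 5 * exp(-(x - 15)^2 / 50) + 9 * exp(-(x - 45)^2 / 50) +
    4 * exp(-(x - 75)^2 / 50)
  img3 <- matrix(rep(row_prof, each = 20), 20, 90)
  p3 <- fos_row_profile(img3, n_bins = 30)
  expect_equal(p3$mean, oracle_profile(img3, matrix(TRUE, 20, 90), 30, "col"))
  expect_error(fos_row_profile(matrix(0, 10, 30)), "zero")
})

test_that("fos ratios count surround vs principal cells", {
  principal <- matrix(FALSE, 40, 40); principal[16:25, 16:25] <- TRUE
  surround <- matrix(FALSE, 40, 40); surround[1:10, ] <- TRUE
  inside <- tibble::tibble(x = runif(10, 16, 25), y = runif(10, 16, 25))
  outside <- tibble::tibble(x = runif(20, 1, 40), y = runif(20, 1, 10))
  expect_equal(fos_ratios(inside, principal, surround)$count_ratio, 0)
  both <- rbind(inside, outside)
  r <- fos_ratios(both, principal, surround)
  expect_equal(r$count_ratio, 2)
  expect_warning(r0 <- fos_ratios(outside, principal, surround), "undefined")
  expect_true(is.na(r0$count_ratio))
  expect_error(fos_ratios(both, principal, principal), "disjoint")
})

test_that("generated barrel images yield the density-implied fos ratio", {
  bi <- simulate_barrel_image(
    barrel_sim_spec(cells_inside = 400, cells_outside = 200, seed = 12)
  )
  r <- fos_ratios(bi$cells, bi$rois$principal, bi$rois$surround)
  expected <- ground_truth(bi)$expected_outside_inside_ratio
  se <- expected * sqrt(1 / 1600 + 1 / 400)
  expect_lt(abs(r$count_ratio - expected), 4 * se)
})

test_that("group heatmaps average Otsu-binarized images", {
  blob <- matrix(0, 30, 30); blob[10:20, 10:20] <- 1
  noisy <- blob * 100 + matrix(runif(900, 0, 5), 30, 30)
  h1 <- group_heatmap(list(noisy, noisy))
  expect_equal(h1, (noisy > barrelquant:::otsu_threshold(noisy)) * 1)
  comp <- list(blob, 1 - blob)
  expect_true(all(group_heatmap(comp) == 0.5))
  # blob present at this location in k of n images -> interior ~ k/n
  other <- matrix(0, 30, 30); other[1:6, 1:6] <- 1
  other_noisy <- other * 100 + matrix(runif(900, 0, 5), 30, 30)
  imgs <- c(replicate(3, noisy, simplify = FALSE),
            replicate(2, other_noisy, simplify = FALSE))
  h <- group_heatmap(imgs)
  expect_equal(mean(h[12:18, 12:18]), 3 / 5, tolerance = 0.05)
  expect_error(group_heatmap(list()), "non-empty")
})
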