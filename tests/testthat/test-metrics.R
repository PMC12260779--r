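test_that("contrast follows the 5-bin histogram definition", {
  # ROI two rows of {1,1,3,3}: profile along the long axis is {1,1,3,3}
  img <- matrix(0, 10, 10)
  img[3:4, 3:6] <- rep(c(1, 1, 3, 3), each = 2)
  ct <- measure_contrast(img, roi_rect(c(2, 2), 2, 4, "boundary"))
  expect_equal(ct$beta_bar_max, 3)
  expect_equal(ct$beta_bar_min, 1)
  expect_equal(ct$C, 0.5)
  expect_false(ct$degenerate)
  # constant profile degenerates to C = 0 with a flag
  cc <- measure_contrast(matrix(2, 8, 8), roi_rect(c(0, 0), 2, 8, "boundary"))
  expect_equal(cc$C, 0)
  expect_true(cc$degenerate)
})

test_that("contrast matches an independent brute-force binning oracle", {
  brute_contrast <- function(profile) {
    lo <- min(profile); hi <- max(profile)
    wdt <- (hi - lo) / 5
    bins <- integer(length(profile))
    for (i in seq_along(profile)) {
      b <- 1L
      while (b < 5L && profile[i] >= lo + b * wdt) b <- b + 1L
      bins[i] <- b
    }
    m_top <- mean(profile[bins == 5L]); m_bot <- mean(profile[bins == 1L])
    (m_top - m_bot) / (m_top + m_bot)
  }
  for (seed in 1:3) {
    set.seed(seed)
    x <- seq(-6, 6, length.out = 200)
    prof <- 1 / (1 + exp(-x)) + rnorm(200, 0, 0.05) + 1
    img <- matrix(rep(prof, each = 3), nrow = 3)   # 3 x 200, average rows
    ct <- measure_contrast(img, roi_rect(c(0, 0), 3, 200, "boundary"))
    expect_equal(ct$C, brute_contrast(colMeans(img)), tolerance = 1e-12)
  }
})

test_that("flat-region SNR is mean over (n-1) standard deviation", {
  img <- matrix(c(4, 6), 64, 64)   # alternating by rows
  sn <- measure_snr(img, roi_rect(c(0, 0), 64, 64, "flat"))
  expect_equal(sn$mean, 5)
  expect_lt(abs(sn$sd - 1), 1e-3)
  expect_equal(sn$snr, 5, tolerance = 1e-3)
  # seeded Gaussian field: SNR 5 +- 0.15 at 128^2 samples
  set.seed(11)
  g <- matrix(rnorm(128^2, 10, 2), 128, 128)
  sg <- measure_snr(g, roi_rect(c(0, 0), 128, 128, "flat"))
  expect_equal(sg$snr, 5, tolerance = 0.03)
  # scale invariance
  s2 <- measure_snr(7.3 * g, roi_rect(c(0, 0), 128, 128, "flat"))
  expect_equal(s2$snr, sg$snr)
  expect_error(measure_snr(matrix(1, 8, 8), roi_rect(c(0, 0), 8, 8, "flat")),
               class = "pbct_infinite_snr")
  # brute-force loop oracle on random fixtures
  for (seed in 1:3) {
    set.seed(seed)
    m <- matrix(runif(16 * 16, 1, 2), 16, 16)
    sm <- measure_snr(m, roi_rect(c(0, 0), 16, 16, "flat"))
    v <- as.numeric(m); mu <- sum(v) / length(v)
    s <- sqrt(sum((v - mu)^2) / (length(v) - 1))
    expect_equal(sm$snr, mu / s, tolerance = 1e-12)
  }
})

test_that("CNR composes contrast and adjacent-flat SNR and is scale-free", {
  set.seed(12)
  img <- matrix(rnorm(96 * 96, 10, 1), 96, 96)
  img[41:96, ] <- img[41:96, ] + 20    # boundary along rows at row 40/41
  bnd <- roi_rect(c(30, 20), 20, 10, "boundary")  # long axis vertical
  flt <- roi_rect(c(30, 10), 10, 10, "flat")      # adjacent to the left
  cn <- measure_cnr(img, bnd, flt)
  expect_equal(cn$cnr, cn$contrast$C * cn$snr$snr)
  cn2 <- measure_cnr(7.3 * img, bnd, flt)
  expect_lt(abs(cn2$cnr - cn$cnr) / cn$cnr, 1e-10)
  # zero-contrast boundary
  flat_img <- matrix(rnorm(96 * 96, 10, 1e-6), 96, 96)
  flat_img[31:50, 21:30] <- 10   # exactly constant ROI
  cz <- measure_cnr(flat_img, bnd, flt)
  expect_equal(cz$cnr, 0)
  # adjacency is validated, not inferred
  far <- roi_rect(c(0, 60), 10, 10, "flat")
  expect_error(measure_cnr(img, bnd, far), "adjacent")
})

test_that("noise power spectrum is flat for white noise and peaked for ramp noise", {
  set.seed(13)
  img <- matrix(rnorm(256 * 256), 256, 256)
  rects <- grid_of_rois(256, 32, 8)   # 64 ROIs of 32^2
  np <- nps_1d(img, rects)
  expect_true(np$flat_spectrum)
  prof <- np$nps[-1]
  expect_lt(max(abs(prof - mean(prof))) / mean(prof), 0.10)
  # ramp-filtered noise: reconstruct a pure-noise sinogram with ram-lak FBP
  set.seed(14)
  sino <- matrix(rnorm(180 * 128), 180, 128)
  fb <- fbp_slice(sino, seq(0, 179, by = 1), "ramlak", 1e-4)
  inner <- grid_of_rois(64, 32, 2)
  inner <- lapply(inner, function(r) roi_rect(r$origin + 32, 32, 32, "flat"))
  npr <- nps_1d(fb, inner)
  expect_gt(npr$peak_freq, 0.25 / 2)   # upper half-band (Nyquist = 0.5)
  expect_error(nps_1d(matrix(0, 64, 64), list(roi_rect(c(0, 0), 32, 32, "flat"))),
               "zero")
  expect_error(nps_1d(img, list(roi_rect(c(0, 0), 8, 8, "flat"))), "16")
})

test_that("resolution estimator recovers a known Gaussian blur", {
  for (sigma in c(1.5, 3)) {
    set.seed(20 + sigma)
    img <- fft_gaussian_blur(matrix(rnorm(512 * 512), 512, 512), sigma)
    rects <- grid_of_rois(512, 64, 8)   # 64 ROIs of 64^2
    rr <- resolution_from_noise(img, rects, pixel_size_m = 1e-4)
    expect_equal(rr$res_px, 2 * sigma, tolerance = 0.10)
    expect_equal(rr$res_m, rr$res_px * 1e-4)
  }
})

test_that("resolution estimator matches the closed-form Gaussian MTF", {
  # a centred Gaussian bump: its FFT magnitude is exactly the Gaussian MTF of
  # a PSF with the same sigma, so the estimator must return 2 sigma
  sigma <- 2
  n <- 64
  x <- seq_len(n) - (n / 2 + 1)
  bump <- exp(-outer(x^2, x^2, `+`) / (2 * sigma^2))
  rr <- resolution_from_noise(bump, list(roi_rect(c(0, 0), n, n, "flat")),
                              window = "none")
  expect_equal(rr$res_px, 2 * sigma, tolerance = 0.01)
})

test_that("blur-recovery holds across sigma with the estimator's median ratio", {
  ratios <- vapply(c(1, 1.5, 2, 3), function(sigma) {
    set.seed(30)
    img <- fft_gaussian_blur(matrix(rnorm(256 * 256), 256, 256), sigma)
    rects <- grid_of_rois(256, 64, 4)
    resolution_from_noise(img, rects)$res_px / (2 * sigma)
  }, numeric(1))
  expect_gte(median(ratios), 0.9)
  expect_lte(median(ratios), 1.1)
})

test_that("intrinsic quality follows SNR/Res^1.5 and the dose scaling", {
  iq <- intrinsic_quality(8, 2)
  expect_equal(iq$snr_over_res15, 8 / 2^1.5)
  q1 <- intrinsic_quality(8, 2, dose_mGy = 1)$qs
  q4 <- intrinsic_quality(8, 2, dose_mGy = 4)$qs
  expect_equal(q4 / q1, 0.5)
  expect_error(intrinsic_quality(8, 0), "res")
})

test_that("SNR/Res^1.5 is approximately invariant under linear filtering", {
  set.seed(40)
  base <- fft_gaussian_blur(matrix(rnorm(256 * 256, 0, 1), 256, 256), 1) + 10
  blurred <- fft_gaussian_blur(base - mean(base), 1) + mean(base)
  rects <- grid_of_rois(256, 64, 4)
  fr <- roi_rect(c(0, 0), 64, 64, "flat")
  m1 <- list(snr = measure_snr(base, fr)$snr,
             res = resolution_from_noise(base, rects)$res_px)
  m2 <- list(snr = measure_snr(blurred, fr)$snr,
             res = resolution_from_noise(blurred, rects)$res_px)
  iq1 <- m1$snr / m1$res^1.5
  iq2 <- m2$snr / m2$res^1.5
  expect_gt(abs(m2$snr - m1$snr) / m1$snr, 0.30)   # SNR moves a lot
  expect_lt(abs(iq2 - iq1) / iq1, 0.15)            # the ratio barely moves
})

test_that("metric bundles keep the CNR identity", {
  set.seed(41)
  img <- matrix(rnorm(96 * 96, 10, 1), 96, 96)
  img[, 49:96] <- img[, 49:96] + 15
  bnd <- roi_rect(c(40, 38), 10, 20, "boundary")
  flt <- roi_rect(c(30, 38), 10, 20, "flat")
  mb <- measure_metrics(img, bnd, flt, voxel_size_m = 1e-4)
  expect_equal(mb$CNR, mb$C * mb$SNR)
  expect_equal(mb$snr_over_res15, mb$SNR / mb$Res_px^1.5)
})
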