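# FBP and gridding share the disk fixture; 1200 noiseless projections
d1200 <- NULL
get_d1200 <- function() {
  if (is.null(d1200)) d1200 <<- disk_sinogram(n = 128, n_angles = 1200)
  d1200
}

test_that("FBP reconstructs a uniform disk quantitatively", {
  d <- get_d1200()
  fb <- fbp_slice(d$sino, d$angles, "ramlak", d$pixel)
  img <- disk_image(d$n, d$radius, d$beta0)
  xs <- seq_len(d$n) - (d$n + 1) / 2
  cen <- outer(xs^2, xs^2, `+`) <= 20^2
  expect_equal(mean(fb$beta[cen]) / d$beta0, 1, tolerance = 0.02)
  expect_lt(sqrt(mean((fb$beta[cen] - d$beta0)^2)) / d$beta0, 0.05)
  # Hamming variant smooths but stays quantitative in the interior
  fh <- fbp_slice(d$sino, d$angles, "hamming", d$pixel)
  expect_equal(mean(fh$beta[cen]) / d$beta0, 1, tolerance = 0.02)
})

test_that("FBP is linear and rejects degenerate inputs", {
  d <- disk_sinogram(n = 64, n_angles = 90)
  z <- fbp_slice(matrix(0, 90, 64), d$angles, "hamming", d$pixel)
  expect_true(all(z$beta == 0))
  f1 <- fbp_slice(d$sino, d$angles, "hamming", d$pixel)
  f2 <- fbp_slice(3.7 * d$sino, d$angles, "hamming", d$pixel)
  expect_equal(f2$beta, 3.7 * f1$beta, tolerance = 1e-12)
  set.seed(4)
  s2 <- matrix(rnorm(90 * 64), 90, 64) * 1e-12
  fa <- fbp_slice(d$sino + 2 * s2, d$angles, "ramlak", d$pixel)$beta
  fb_ <- fbp_slice(d$sino, d$angles, "ramlak", d$pixel)$beta
  fc <- fbp_slice(s2, d$angles, "ramlak", d$pixel)$beta
  expect_lt(max(abs(fa - fb_ - 2 * fc)) / max(abs(fa)), 1e-8)
  expect_error(fbp_slice(d$sino[1, , drop = FALSE], 0, "hamming", d$pixel),
               "two projection")
})

test_that("unregularized gridding agrees with ram-lak FBP on the disk", {
  d <- get_d1200()
  fb <- fbp_slice(d$sino, d$angles, "ramlak", d$pixel)
  gr <- gridding_recon(d$sino, d$angles, gridding_params(nsr = 0), d$pixel)
  rmse <- sqrt(mean((gr$beta - fb$beta)^2))
  expect_lt(rmse / d$beta0, 0.02)
})

test_that("gridding damping is monotone in the noise-to-signal ratio", {
  d <- disk_sinogram(n = 64, n_angles = 180)
  set.seed(8)
  noisy <- d$sino + matrix(rnorm(length(d$sino)), nrow(d$sino)) * 0.05 *
    max(d$sino)
  hf_power <- function(img) {
    sp <- Mod(stats::fft(img - mean(img)))^2
    u <- pbct:::fft_freq(64)
    sum(sp[outer(u^2, u^2, `+`) > 0.25^2])
  }
  p <- vapply(c(0, 0.05, 0.2), function(nsr) {
    hf_power(gridding_recon(noisy, d$angles, gridding_params(nsr = nsr),
                            d$pixel)$beta)
  }, numeric(1))
  expect_true(all(diff(p) <= 0))
  z <- gridding_recon(matrix(0, 180, 64), d$angles, gridding_params(), d$pixel)
  expect_true(all(z$beta == 0))
  expect_error(gridding_params(nsr = -0.1), "nsr")
})

test_that("gridding is linear", {
  d <- disk_sinogram(n = 64, n_angles = 120)
  set.seed(5)
  s2 <- matrix(rnorm(120 * 64), 120, 64) * 1e-12
  gp <- gridding_params(nsr = 0.05)
  ga <- gridding_recon(d$sino + 2 * s2, d$angles, gp, d$pixel)$beta
  gb <- gridding_recon(d$sino, d$angles, gp, d$pixel)$beta
  gc <- gridding_recon(s2, d$angles, gp, d$pixel)$beta
  expect_lt(max(abs(ga - gb - 2 * gc)) / max(abs(ga)), 1e-8)
})

test_that("every reconstruction records its provenance", {
  d <- disk_sinogram(n = 64, n_angles = 90)
  fb <- fbp_slice(d$sino, d$angles, "hamming", d$pixel)
  expect_equal(fb$params_used$filter, "hamming")
  gr <- gridding_recon(d$sino, d$angles, gridding_params(), d$pixel)
  expect_equal(gr$params_used$nsr, 0.05)
  cs <- csart_reconstruct(d$sino, d$angles,
                          csart_params(n_iter = 1,
                                       bilateral = bilateral_params(w = 0)),
                          d$pixel)
  pu <- cs$params_used
  expect_true(all(c("schedule", "order_seed", "bilateral",
                    "residual_norms") %in% names(pu)))
  expect_equal(pu$schedule_samples[c(1, 3)], c(0, 0))
})
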