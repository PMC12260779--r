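test_that("flat/dark correction follows (P - D)/(F - D)", {
  P <- matrix(150, 8, 8); Fm <- matrix(200, 8, 8); D <- matrix(100, 8, 8)
  expect_equal(flat_dark_correct(P, Fm, D), matrix(0.5, 8, 8))
  expect_equal(flat_dark_correct(Fm, Fm, matrix(0, 8, 8)), matrix(1, 8, 8))
  expect_equal(flat_dark_correct(D, Fm, D), matrix(0, 8, 8))
  # stack averaging: two flats averaging to 200
  fl <- array(0, dim = c(2, 8, 8)); fl[1, , ] <- 150; fl[2, , ] <- 250
  expect_equal(flat_dark_correct(P, fl, D), matrix(0.5, 8, 8))
  bad <- Fm; bad[3, 4] <- 50
  expect_error(flat_dark_correct(P, bad, D), "1 pixel")
})

test_that("Paganin filter is the identity at gamma 0 and preserves means", {
  set.seed(1)
  Tm <- matrix(0.5 + 0.3 * runif(64 * 64), 64, 64)
  p0 <- phase_retrieval_params(gamma = 0)
  expect_equal(paganin_filter(Tm, p0), Tm)
  pc <- phase_retrieval_params(gamma = 275)
  expect_equal(paganin_filter(matrix(0.7, 32, 32), pc), matrix(0.7, 32, 32))
  out <- paganin_filter(Tm, pc)
  expect_lt(abs(mean(out) - mean(Tm)) / mean(Tm), 1e-10)
  expect_lte(var(as.numeric(out)), var(as.numeric(Tm)))
  bad <- Tm; bad[1, 1] <- NaN
  expect_error(paganin_filter(bad, pc), "finite")
})

test_that("higher gamma removes more high-frequency power", {
  set.seed(2)
  Tm <- matrix(0.6 + 0.2 * runif(64 * 64), 64, 64)
  hf_power <- function(x) {
    sp <- Mod(stats::fft(x - mean(x)))^2
    u <- pbct:::fft_freq(64)
    mask <- outer(u^2, u^2, `+`) > 0.25^2   # above half-Nyquist (cycles/px)
    sum(sp[mask])
  }
  powers <- vapply(c(0, 50, 275, 550), function(g) {
    hf_power(paganin_filter(Tm, phase_retrieval_params(gamma = g)))
  }, numeric(1))
  expect_true(all(diff(powers) < 0))
})

test_that("TIE simulation and Paganin retrieval are exact inverses", {
  lam <- wavelength_from_energy(32)
  rp <- effective_propagation_distance(143, 6)
  w <- 1e-4
  n <- 128
  x <- (seq_len(n) - (n + 1) / 2) * w
  r2 <- outer(x^2, x^2, `+`)
  R <- 0.004
  pb <- ifelse(r2 < R^2, 2 * sqrt(pmax(R^2 - r2, 0)), 0) * 1.5e-10
  Tc <- exp(-(4 * pi / lam) * pb)
  gam <- 550
  q <- pi * gam * lam * rp
  fwd <- pbct:::fourier_filter(Tc, function(u2) 1 + q * u2, w)
  bk <- paganin_filter(fwd, phase_retrieval_params(
    gamma = gam, effective_distance_m = rp, wavelength_m = lam,
    pixel_size_m = w))
  expect_lt(max(abs(bk - Tc) / Tc), 1e-8)
})

test_that("projected beta inverts Beer's law with a positivity floor", {
  expect_equal(as.numeric(to_projected_beta(matrix(1, 2, 2), 1e-10)),
               rep(0, 4))
  out <- to_projected_beta(exp(-1), 4 * pi)
  expect_equal(as.numeric(out), 1)
  cl <- to_projected_beta(matrix(c(0.5, -0.2), 1, 2), 1e-10)
  expect_equal(attr(cl, "clipped"), 1L)
  expect_true(all(is.finite(cl)))
})

test_that("the full noiseless chain reproduces the forward sinogram", {
  ph <- make_phantom(breast_phantom_spec(c(64, 64, 1), n_calcs = 0))
  g <- scan_geometry(angles_deg = seq(0, 170, by = 10))
  ps <- simulate_projections(ph, g, 1e6, "tie", noise = FALSE)
  sn <- retrieve_projections(ps, gamma = ph$spec$gamma_true)
  truth <- project_parallel(ph, g$angles_deg)
  rel_rmse <- sqrt(mean((sn$proj - truth)^2)) / sqrt(mean(truth^2))
  expect_lt(rel_rmse, 1e-6)
  # central disk value matches the analytic chord within 1%
  d <- disk_sinogram(n = 129, radius = 40, n_angles = 8)
  ph2 <- array(disk_image(129, 40, 1.6e-10), dim = c(129, 129, 1))
  sp2 <- phantom_spec(container_diameter_m = 128 * 1e-4, grid_shape = c(129, 129, 1))
  # retrieved projected beta of a disk via the simulate/retrieve chain
  spd <- phantom_spec(container_diameter_m = 82 * 1e-4,
                      grid_shape = c(129, 129, 1),
                      tissue_components = list(
                        list(label = "adipose", type = "cylinder",
                             center = c(0, 0), radius = 40e-4, beta = 1.6e-10)))
  phd <- make_phantom(spd)
  gd <- scan_geometry(angles_deg = 0)
  psd <- simulate_projections(phd, gd, 1e6, "tie", noise = FALSE)
  snd <- retrieve_projections(psd, gamma = phd$spec$gamma_true)
  expect_equal(snd$proj[1, 65, 1], 2 * 40e-4 * 1.6e-10, tolerance = 0.01)
})
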