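test_that("relaxation schedule is zero at both ends and peaks at the ramp", {
  s <- relaxation_schedule(eta_max = 0.8, ramp_steps = 50, total_steps = 1000)
  expect_equal(relaxation_factor(0, s), 0)
  expect_equal(relaxation_factor(999, s), 0)
  expect_equal(relaxation_factor(50, s), 0.8)
  steps <- 0:999
  eta <- relaxation_factor(steps, s)
  expect_true(all(eta >= 0 & eta <= 0.8))
  # piecewise linear: increasing then decreasing
  expect_true(all(diff(eta[1:51]) > 0))
  expect_true(all(diff(eta[52:1000]) < 0))
  expect_error(relaxation_factor(-1, s), "range")
  expect_error(relaxation_factor(1000, s), "range")
})

test_that("bilateral filter honours its blend and degeneracy contracts", {
  set.seed(6)
  v <- matrix(runif(32 * 32), 32, 32)
  p0 <- bilateral_params(sigma_xy = 2, sigma_z = 1, sigma_v = 0.1, w = 0)
  expect_identical(bilateral_filter_3d(v, p0), v)
  pc <- bilateral_params(sigma_xy = 2, sigma_z = 1, sigma_v = 0.1, w = 0.5)
  const <- matrix(5, 16, 16)
  expect_identical(bilateral_filter_3d(const, pc), const)
  expect_error(bilateral_filter_3d(matrix(c(1, NA), 2, 2), pc), "finite")
  expect_error(bilateral_params(w = 1.5), "w")
})

test_that("with a huge intensity width the bilateral is a Gaussian smoother", {
  set.seed(7)
  v <- matrix(runif(48 * 48), 48, 48)
  sig <- 2
  pg <- bilateral_params(sigma_xy = sig, sigma_z = 1, sigma_v = 1e9, w = 1)
  got <- bilateral_filter_3d(v, pg)
  # oracle: separable truncated-Gaussian convolution with border
  # renormalization (numerator and normalizer convolved separately)
  r <- ceiling(3 * sig)
  k <- exp(-((-r):r)^2 / (2 * sig^2))
  conv1 <- function(m, k, along) {
    out <- matrix(0, nrow(m), ncol(m))
    r <- (length(k) - 1) / 2
    for (o in -r:r) {
      w <- k[o + r + 1]
      if (along == 1) {
        src <- seq_len(nrow(m)) + o
        ok <- src >= 1 & src <= nrow(m)
        out[ok, ] <- out[ok, ] + w * m[src[ok], ]
      } else {
        src <- seq_len(ncol(m)) + o
        ok <- src >= 1 & src <= ncol(m)
        out[, ok] <- out[, ok] + w * m[, src[ok]]
      }
    }
    out
  }
  num <- conv1(conv1(v, k, 1), k, 2)
  den <- conv1(conv1(matrix(1, 48, 48), k, 1), k, 2)
  expect_lt(max(abs(got - num / den)) / max(abs(got)), 1e-6)
})

test_that("cSART converges on noiseless data and is deterministic", {
  d <- disk_sinogram(n = 128, n_angles = 360)
  p <- csart_params(bilateral = bilateral_params(w = 0))
  cs <- csart_reconstruct(d$sino, d$angles, p, d$pixel)
  rn <- cs$params_used$residual_norms
  expect_lt(rn[5], rn[1])            # residual shrinks across iterations
  expect_true(all(diff(rn) < 0))
  z <- csart_reconstruct(matrix(0, 360, 128), d$angles, p, d$pixel)
  expect_true(all(z$beta == 0))
  cs2 <- csart_reconstruct(d$sino, d$angles, p, d$pixel)
  expect_identical(cs$beta, cs2$beta)
  p2 <- csart_params(bilateral = bilateral_params(w = 0), order_seed = 99)
  cs3 <- csart_reconstruct(d$sino, d$angles, p2, d$pixel)
  expect_false(identical(cs$beta, cs3$beta))
})

test_that("plain constant-relaxation SART approaches the FBP solution", {
  d <- disk_sinogram(n = 128, n_angles = 360)
  img <- disk_image(d$n, d$radius, d$beta0)
  p <- csart_params(bilateral = bilateral_params(w = 0))
  cs <- csart_reconstruct(d$sino, d$angles, p, d$pixel, constant_eta = 0.25)
  fb <- fbp_slice(d$sino, d$angles, "hamming", d$pixel)
  rmse <- function(x) sqrt(mean((x - img)^2))
  expect_lte(rmse(cs$beta), 1.5 * rmse(fb$beta))
})
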