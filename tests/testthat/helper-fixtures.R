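# Shared fixtures, built in code at test time.

# uniform disk image (beta units) and its sinogram
disk_image <- function(n = 128, radius = 40, beta0 = 1.6e-10) {
  xs <- seq_len(n) - (n + 1) / 2
  (outer(xs^2, xs^2, `+`) <= radius^2) * beta0
}

disk_sinogram <- function(n = 128, radius = 40, beta0 = 1.6e-10,
                          n_angles = 1200, pixel = 1e-4) {
  ang <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  sino <- project_parallel(disk_image(n, radius, beta0), ang, pixel)[, , 1]
  list(sino = sino, angles = ang, pixel = pixel, beta0 = beta0,
       radius = radius, n = n)
}

# small breast-like phantom and a noisy desk-scale scan (memoised per session)
.fixture_env <- new.env(parent = emptyenv())

desk_phantom <- function() {
  if (is.null(.fixture_env$phantom))
    .fixture_env$phantom <- make_phantom(breast_phantom_spec())
  .fixture_env$phantom
}

desk_scan <- function(seed = 3) {
  key <- paste0("scan", seed)
  if (is.null(.fixture_env[[key]])) {
    g <- scan_geometry(angles_deg = seq(0, 179.5, by = 0.5))
    ps <- simulate_projections(desk_phantom(), g, 300, "tie", seed = seed)
    .fixture_env[[key]] <- retrieve_projections(ps, gamma = 275)
  }
  .fixture_env[[key]]
}

desk_rois <- function() {
  if (is.null(.fixture_env$rois))
    .fixture_env$rois <- suggest_rois(desk_phantom())
  .fixture_env$rois
}

# Gaussian blur via FFT (periodic), used as an independent smoothing oracle
fft_gaussian_blur <- function(img, sigma) {
  n1 <- nrow(img); n2 <- ncol(img)
  u1 <- pbct:::fft_freq(n1); u2 <- pbct:::fft_freq(n2)
  H <- exp(-2 * pi^2 * sigma^2 * outer(u1^2, u2^2, `+`))
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / length(img)
}

grid_of_rois <- function(n_side, roi, count_side) {
  rects <- list()
  for (i in seq_len(count_side) - 1)
    for (j in seq_len(count_side) - 1)
      rects[[length(rects) + 1]] <- roi_rect(c(i * roi, j * roi), roi, roi, "flat")
  rects
}
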