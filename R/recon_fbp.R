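# Extract a single-slice sinogram matrix (n_angles x n_det) from either a
# sinogram_set or a bare matrix.
.sino_slice <- function(sinogram, slice = 1L) {
  if (inherits(sinogram, "sinogram_set")) {
    d <- dim(sinogram$proj)
    matrix(sinogram$proj[, , slice], d[1], d[2])
  } else as.matrix(sinogram)
}

.recon_volume <- function(beta, voxel_size_m, algorithm, params_used) {
  structure(list(beta = beta, voxel_size_m = voxel_size_m,
                 algorithm = algorithm, params_used = params_used),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  d <- dim(x$beta)
  if (length(d) == 2) d <- c(d, 1)
  cat(sprintf("recon_volume (%s): %d x %d x %d voxels at %g um\n",
              x$algorithm, d[1], d[2], d[3], x$voxel_size_m * 1e6))
  invisible(x)
}

# Band-limited ramp filter response with optional apodization window.  The
# ramp is built from its exact spatial kernel (1/(4 tau^2) at 0, 0 at even
# lags, -1/(pi n tau)^2 at odd lags) rather than by sampling |u|, which keeps
# the DC response correct and avoids interior cupping.
.fbp_filter_profile <- function(L, pixel_m, filter_name) {
  n <- c(seq.int(0L, ceiling(L / 2) - 1L), seq.int(-floor(L / 2), -1L))
  h <- numeric(L)
  h[n == 0] <- 1 / (4 * pixel_m^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd] * pixel_m)^2
  Hramp <- Re(stats::fft(h)) * pixel_m
  u <- fft_freq(L, pixel_m)
  un <- 1 / (2 * pixel_m)
  win <- switch(filter_name,
                ramlak = rep(1, L),
                hamming = 0.54 + 0.46 * cos(pi * u / un),
                stop("unknown filter: ", filter_name, call. = FALSE))
  Hramp * win
}

#' Filtered back projection of one sinogram slice
#'
#' Classical parallel-beam FBP: each projection is ramp-filtered in the
#' Fourier domain (optionally apodized with a Hamming window, the setting used
#' for the comparison study), then backprojected with the standard
#' `pi / n_angles` normalization. The operator is linear and returns the
#' reconstruction in beta units.
#'
#' @param sinogram A `sinogram_set` or a matrix `(n_angles x n_det)` of
#'   projected beta (m).
#' @param angles_deg Projection angles (degrees); taken from the
#'   `sinogram_set` when omitted.
#' @param filter_name `"hamming"` (default) or `"ramlak"`.
#' @param pixel_size_m Detector pitch (m); taken from the `sinogram_set` when
#'   omitted.
#' @param slice Slice (detector row) to reconstruct from a multi-row set.
#' @return A `"recon_volume"` with a 2D `beta` slice.
#' @export
fbp_slice <- function(sinogram, angles_deg = NULL, filter_name = c("hamming", "ramlak"),
                      pixel_size_m = NULL, slice = 1L) {
  filter_name <- match.arg(filter_name)
  if (inherits(sinogram, "sinogram_set")) {
    if (is.null(angles_deg)) angles_deg <- sinogram$angles_deg
    if (is.null(pixel_size_m)) pixel_size_m <- sinogram$pixel_size_m
  }
  .stop_if(is.null(angles_deg) || is.null(pixel_size_m),
           "'angles_deg' and 'pixel_size_m' are required for a bare matrix")
  sino <- .sino_slice(sinogram, slice)
  nang <- nrow(sino); ndet <- ncol(sino)
  .stop_if(nang < 2, "FBP needs at least two projection angles")
  .stop_if(nang != length(angles_deg), "angle count does not match the sinogram")
  filt <- .fbp_filter_sino(sino, pixel_size_m, filter_name)
  th <- angles_deg * pi / 180
  img <- cpp_backproject(filt, cos(th), sin(th), ndet, ndet) * (pi / nang)
  img[!.circle_mask(ndet)] <- 0
  .recon_volume(img, pixel_size_m, "fbp",
                list(filter = filter_name, angles_deg = angles_deg,
                     pixel_size_m = pixel_size_m))
}

# Row-wise ramp filtering of a sinogram (zero-padded to the next power of two
# at least twice the detector width).
.fbp_filter_sino <- function(sino, pixel_m, filter_name) {
  nang <- nrow(sino); ndet <- ncol(sino)
  L <- 2^ceiling(log2(2 * ndet))
  H <- .fbp_filter_profile(L, pixel_m, filter_name)
  sp <- matrix(0, L, nang)
  sp[seq_len(ndet), ] <- t(sino)
  ft <- stats::mvfft(sp) * H
  q <- Re(stats::mvfft(ft, inverse = TRUE)) / L
  t(q[seq_len(ndet), , drop = FALSE])
}

# standard reconstruction-circle mask: parallel-beam data only determine the
# image inside the inscribed circle; outside it is set to zero
.circle_mask <- function(n) {
  x <- seq_len(n) - (n + 1) / 2
  outer(x^2, x^2, `+`) <= (n / 2)^2
}
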