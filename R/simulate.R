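#' Simulate a propagation-based CT acquisition
#'
#' Full forward model from a voxelized phantom to detector photon counts:
#' parallel-beam line integrals of beta, contact transmission
#' `T = exp(-(4*pi/lambda) * integral(beta) dz)`, optional free-space
#' propagation, Poisson photon noise at a fixed fluence budget, and flat/dark
#' calibration frames.
#'
#' Propagation models:
#' \describe{
#'   \item{`"contact"`}{detected intensity equals the contact transmission.}
#'   \item{`"tie"`}{linearized transport-of-intensity forward operator
#'     `I = [1 - (R' * gamma * lambda / (4*pi)) Laplacian] T`, applied in the
#'     Fourier domain as multiplication by `1 + pi * gamma * lambda * R' *
#'     |u|^2` — the exact forward twin of the Paganin filter, so retrieval
#'     with the same gamma inverts it to machine precision.}
#'   \item{`"fresnel"`}{angular-spectrum propagation of the complex
#'     transmission `sqrt(T) * exp(i * phi)` with `phi = (gamma/2) * log(T)`
#'     over the effective distance R'.}
#' }
#'
#' Noise uses one master seed fanned out to deterministic per-frame
#' substreams, so earlier frames are unchanged when the number of angles
#' changes.
#'
#' @param phantom A [make_phantom()] result.
#' @param geometry A [scan_geometry()]; its pixel pitch must equal the
#'   phantom's voxel pitch (plane-wave beam, one detector column per voxel
#'   column).
#' @param fluence_per_projection Mean photons per detector pixel per
#'   projection (before the object).
#' @param propagation_model `"tie"` (default), `"contact"` or `"fresnel"`.
#' @param seed Master RNG seed for all noise draws.
#' @param noise If `FALSE`, counts are the noiseless expected values.
#' @param n_flats,n_darks Number of calibration frames.
#' @param dark_offset Constant dark-current offset in counts (default 0:
#'   pure Poisson counting).
#' @param vertical_profile Apply the Gaussian vertical beam roll-off from
#'   `geometry$vertical_profile_sigma_m` (only meaningful for multi-row
#'   frames; default off — 2D slice simulation).
#' @return An object of class `"projection_set"`: counts/flats/darks arrays
#'   (`n_frames x n_det x n_rows`), geometry, fluence, model, gamma, seed and
#'   the number of negativity-clipped pixels.
#' @export
simulate_projections <- function(phantom, geometry, fluence_per_projection,
                                 propagation_model = c("tie", "contact", "fresnel"),
                                 seed = 1L, noise = TRUE,
                                 n_flats = 20L, n_darks = 20L,
                                 dark_offset = 0,
                                 vertical_profile = FALSE) {
  propagation_model <- match.arg(propagation_model)
  .stop_if(!inherits(phantom, "phantom_volume"), "'phantom' must be a phantom_volume")
  .stop_if(!inherits(geometry, "scan_geometry"), "'geometry' must be a scan_geometry")
  .stop_if(fluence_per_projection <= 0, "'fluence_per_projection' must be positive")
  .stop_if(abs(geometry$pixel_size_m - phantom$voxel_size_m) >
             1e-9 * geometry$pixel_size_m,
           "detector pixel pitch must equal the phantom voxel pitch")
  lambda <- geometry$wavelength_m
  rp <- geometry$effective_distance_m
  gam <- phantom$spec$gamma_true
  w <- geometry$pixel_size_m
  proj <- project_parallel(phantom, geometry$angles_deg)
  nang <- dim(proj)[1]; ndet <- dim(proj)[2]; nz <- dim(proj)[3]
  clipped <- 0L

  intensity <- array(0, dim = dim(proj))
  for (a in seq_len(nang)) {
    Tm <- exp(-(4 * pi / lambda) * proj[a, , ])
    Tm <- matrix(Tm, nrow = ndet, ncol = nz)
    I <- switch(propagation_model,
      contact = Tm,
      tie = fourier_filter(Tm, function(u2) 1 + pi * gam * lambda * rp * u2, w),
      fresnel = {
        phi <- (gam / 2) * log(Tm)
        psi <- sqrt(Tm) * exp(1i * phi)
        psi_r <- fourier_filter(psi, function(u2) exp(-1i * pi * lambda * rp * u2), w)
        Mod(psi_r)^2
      })
    neg <- I < 0
    if (any(neg)) {
      clipped <- clipped + sum(neg)
      I[neg] <- 0
    }
    intensity[a, , ] <- I
  }
  if (clipped > 0)
    warning(sprintf("TIE forward operator produced %d negative pixels (clipped at 0)",
                    clipped))

  vprof <- rep(1, nz)
  if (vertical_profile && !is.null(geometry$vertical_profile_sigma_m) && nz > 1) {
    zc <- .axis_coords(nz, w)
    vprof <- exp(-zc^2 / (2 * geometry$vertical_profile_sigma_m^2))
  }
  beam <- matrix(rep(vprof, each = ndet), ndet, nz) * fluence_per_projection

  counts <- array(0, dim = c(nang, ndet, nz))
  for (a in seq_len(nang)) {
    mu <- intensity[a, , ] * beam
    if (noise) {
      set.seed(frame_seed(seed, a))
      fr <- rpois(length(mu), mu)
      if (dark_offset > 0) fr <- fr + rpois(length(mu), dark_offset)
      counts[a, , ] <- fr
    } else counts[a, , ] <- mu + dark_offset
  }
  flats <- array(0, dim = c(n_flats, ndet, nz))
  for (i in seq_len(n_flats)) {
    if (noise) {
      set.seed(frame_seed(seed, nang + i))
      fr <- rpois(length(beam), beam)
      if (dark_offset > 0) fr <- fr + rpois(length(beam), dark_offset)
      flats[i, , ] <- fr
    } else flats[i, , ] <- beam + dark_offset
  }
  darks <- array(0, dim = c(n_darks, ndet, nz))
  if (dark_offset > 0) {
    for (i in seq_len(n_darks)) {
      if (noise) {
        set.seed(frame_seed(seed, nang + n_flats + i))
        darks[i, , ] <- rpois(ndet * nz, dark_offset)
      } else darks[i, , ] <- dark_offset
    }
  }
  structure(list(counts = counts, flats = flats, darks = darks,
                 geometry = geometry,
                 fluence_per_projection = fluence_per_projection,
                 propagation_model = propagation_model,
                 gamma_true = gam, noise = noise, seed = as.integer(seed),
                 dark_offset = dark_offset, clipped = clipped),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("projection_set: %d projections of %d x %d pixels (%s model)\n",
              d[1], d[2], d[3], x$propagation_model))
  cat(sprintf("  fluence %g ph/px/projection, %d flats, %d darks, noise %s\n",
              x$fluence_per_projection, dim(x$flats)[1], dim(x$darks)[1],
              if (x$noise) "on" else "off"))
  invisible(x)
}
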