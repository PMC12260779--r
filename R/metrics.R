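#' Rectangular region of interest
#'
#' 0-based, half-open rectangle on one slice. `role = "flat"` marks uniform
#' regions used for SNR, noise-power and resolution measurements (128 x 128 px
#' is the working size on thin coronal slices, 64 x 64 on thick axial ones);
#' `role = "boundary"` marks rectangles whose long axis crosses a tissue
#' interface, used for contrast.
#'
#' @param origin `c(row, col)`, 0-based.
#' @param height,width Extent in pixels.
#' @param role `"flat"` or `"boundary"`.
#' @param slice_index Slice the rectangle lives on (1-based), default 1.
#' @return An object of class `"roi_rect"`.
#' @export
roi_rect <- function(origin, height, width, role = c("flat", "boundary"),
                     slice_index = 1L) {
  role <- match.arg(role)
  .stop_if(length(origin) != 2 || any(origin < 0), "'origin' must be c(row, col) >= 0")
  .stop_if(height < 1 || width < 1, "height and width must be >= 1")
  structure(list(slice_index = as.integer(slice_index),
                 origin = as.integer(origin),
                 height = as.integer(height), width = as.integer(width),
                 role = role),
            class = "roi_rect")
}

.roi_extract <- function(image, rect) {
  .stop_if(!inherits(rect, "roi_rect"), "expected an roi_rect")
  r0 <- rect$origin[1]; c0 <- rect$origin[2]
  .stop_if(r0 + rect$height > nrow(image) || c0 + rect$width > ncol(image),
           "ROI does not fit inside the image")
  image[r0 + seq_len(rect$height), c0 + seq_len(rect$width), drop = FALSE]
}

.as_image <- function(x, slice = 1L) {
  if (inherits(x, "recon_volume")) {
    b <- x$beta
    if (length(dim(b)) == 3) b <- b[, , slice]
    return(b)
  }
  as.matrix(x)
}

#' Boundary contrast from a 1D-averaged profile histogram
#'
#' The rectangle's pixel values are averaged along its shorter dimension,
#' giving a 1D profile along the long axis; the profile's range is divided
#' into five equal intervals and the contrast is
#' `C = (m_top - m_bot) / (m_top + m_bot)` with `m_top`, `m_bot` the mean
#' values of the top and bottom bins. Values equal to an interior upper bin
#' edge fall into the higher bin. A degenerate (constant) profile yields
#' `C = 0` with `degenerate = TRUE`.
#'
#' @param image Matrix or `recon_volume`.
#' @param rect A boundary-role [roi_rect()].
#' @return List of class `"contrast_result"`: `C`, `beta_bar_max`,
#'   `beta_bar_min`, `bin_edges`, `profile`, `degenerate`.
#' @export
measure_contrast <- function(image, rect) {
  img <- .as_image(image, rect$slice_index)
  .stop_if(rect$role != "boundary", "contrast needs a boundary-role ROI")
  roi <- .roi_extract(img, rect)
  profile <- if (nrow(roi) >= ncol(roi)) rowMeans(roi) else colMeans(roi)
  .stop_if(length(profile) < 2, "profile must have at least 2 samples")
  rng <- range(profile)
  if (diff(rng) == 0) {
    return(structure(list(C = 0, beta_bar_max = rng[2], beta_bar_min = rng[1],
                          bin_edges = rep(rng[1], 6), profile = profile,
                          degenerate = TRUE),
                     class = "contrast_result"))
  }
  edges <- seq(rng[1], rng[2], length.out = 6)
  bin <- pmin(findInterval(profile, edges), 5L)
  m_bot <- mean(profile[bin == 1L])
  m_top <- mean(profile[bin == 5L])
  structure(list(C = (m_top - m_bot) / (m_top + m_bot),
                 beta_bar_max = m_top, beta_bar_min = m_bot,
                 bin_edges = edges, profile = profile, degenerate = FALSE),
            class = "contrast_result")
}

#' SNR in a flat region
#'
#' Mean over standard deviation (n-1 denominator) inside a flat ROI, relying
#' on spatial ergodicity: spatial statistics of a uniform region stand in for
#' ensemble statistics.
#'
#' @param image Matrix or `recon_volume`.
#' @param rect A flat-role [roi_rect()].
#' @return List of class `"snr_result"`: `snr`, `mean`, `sd`, `roi`.
#' @export
measure_snr <- function(image, rect) {
  img <- .as_image(image, rect$slice_index)
  .stop_if(rect$role != "flat", "SNR needs a flat-role ROI")
  v <- as.numeric(.roi_extract(img, rect))
  s <- sd(v)
  if (s == 0)
    stop(errorCondition("zero standard deviation in flat ROI: SNR is infinite",
                        class = c("pbct_infinite_snr", "error", "condition")))
  structure(list(snr = mean(v) / s, mean = mean(v), sd = s, roi = rect),
            class = "snr_result")
}

# adjacency: the flat ROI must share (part of) an edge with the boundary
# rectangle's top or left side
.is_adjacent <- function(flat, boundary) {
  f_r1 <- flat$origin[1] + flat$height; f_c1 <- flat$origin[2] + flat$width
  b_r0 <- boundary$origin[1]; b_c0 <- boundary$origin[2]
  col_overlap <- flat$origin[2] < b_c0 + boundary$width &&
    boundary$origin[2] < f_c1
  row_overlap <- flat$origin[1] < b_r0 + boundary$height &&
    boundary$origin[1] < f_r1
  (f_r1 == b_r0 && col_overlap) || (f_c1 == b_c0 && row_overlap)
}

#' Contrast-to-noise ratio
#'
#' `CNR = C x SNR`, with the contrast measured across a tissue interface and
#' the SNR measured in a flat region immediately adjacent to the top or left
#' side of the boundary rectangle (adjacency is validated). Dimensionless and
#' invariant under linear intensity scaling.
#'
#' @param image Matrix or `recon_volume`.
#' @param boundary_rect,flat_rect The two [roi_rect()]s.
#' @return List with `cnr`, `contrast`, `snr` components.
#' @export
measure_cnr <- function(image, boundary_rect, flat_rect) {
  .stop_if(!.is_adjacent(flat_rect, boundary_rect),
           "flat ROI must be adjacent to the top or left side of the boundary ROI")
  ct <- measure_contrast(image, boundary_rect)
  sn <- measure_snr(image, flat_rect)
  list(cnr = ct$C * sn$snr, contrast = ct, snr = sn)
}

# mean-subtracted (optionally Hann-windowed) 2D magnitude or power spectra of
# a list of congruent flat ROIs, averaged
.flat_spectra <- function(image, flat_rects, window = c("hann", "none"),
                          power = FALSE) {
  window <- match.arg(window)
  rois <- lapply(flat_rects, function(r) {
    img <- .as_image(image, r$slice_index)
    .roi_extract(img, r)
  })
  d <- dim(rois[[1]])
  .stop_if(!all(vapply(rois, function(r) all(dim(r) == d), logical(1))),
           "all flat ROIs must share the same shape")
  wmat <- if (window == "hann") {
    h1 <- 0.5 - 0.5 * cos(2 * pi * (seq_len(d[1]) - 1) / (d[1] - 1))
    h2 <- 0.5 - 0.5 * cos(2 * pi * (seq_len(d[2]) - 1) / (d[2] - 1))
    outer(h1, h2)
  } else matrix(1, d[1], d[2])
  acc <- matrix(0, d[1], d[2])
  for (r in rois) {
    sp <- Mod(fft2((r - mean(r)) * wmat))
    acc <- acc + if (power) sp^2 else sp
  }
  list(spec = acc / length(rois), dims = d, window = wmat)
}

# radial binning of a 2D spectrum (frequencies in cycles/px); bin width = one
# frequency sample of the first axis
.radial_profile <- function(spec) {
  d <- dim(spec)
  f1 <- fft_freq(d[1]); f2 <- fft_freq(d[2])
  fr <- sqrt(outer(f1^2, f2^2, `+`))
  bw <- 1 / d[1]
  bin <- pmin(floor(fr / bw), floor(0.5 / bw)) + 1L
  num <- tapply(as.numeric(spec), bin, sum)
  cnt <- tapply(rep(1, length(spec)), bin, sum)
  freq <- (as.integer(names(num)) - 0.5) * bw
  freq[1] <- 0
  list(freq = freq, value = as.numeric(num / cnt))
}

#' 1D noise power spectrum of flat regions
#'
#' Mean-subtracted 2D power spectra of the flat ROIs are ensemble-averaged and
#' radially binned to one dimension. The peak frequency is the argmax after a
#' 3-bin moving-average smoothing with the DC bin excluded; a spectrum whose
#' max/median ratio is below 1.2 is flagged flat (peak not meaningful).
#'
#' @param image Matrix or `recon_volume`.
#' @param flat_rects List of congruent flat-role [roi_rect()]s (at least one,
#'   at least 16 x 16 pixels).
#' @param window Apodization window for the spectral estimate (default none:
#'   noise fields carry no edge discontinuity worth trading variance for).
#' @return List of class `"nps_result"`: `freq` (cycles/px), `nps`,
#'   `peak_freq`, `flat_spectrum` flag.
#' @export
nps_1d <- function(image, flat_rects, window = "none") {
  .stop_if(length(flat_rects) < 1, "at least one flat ROI is required")
  .stop_if(flat_rects[[1]]$height < 16 || flat_rects[[1]]$width < 16,
           "flat ROIs must be at least 16 x 16 pixels")
  sp <- .flat_spectra(image, flat_rects, window = window, power = TRUE)
  .stop_if(all(sp$spec == 0), "zero image: noise power spectrum undefined")
  rp <- .radial_profile(sp$spec)
  v <- rp$value[-1]; f <- rp$freq[-1]          # DC excluded
  sm <- stats::filter(v, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- v[is.na(sm)]
  peak_i <- which.max(sm)
  flat_flag <- max(sm) / median(sm) < 1.2
  structure(list(freq = rp$freq, nps = rp$value,
                 peak_freq = f[peak_i], flat_spectrum = flat_flag),
            class = "nps_result")
}

#' Spatial resolution from the noise of flat regions
#'
#' Noise in a flat region is ideal white noise convolved with the system's
#' point-spread function, so the radial width of the averaged magnitude
#' spectrum of flat ROIs measures the MTF width. The width is the
#' dimension-normalized second moment `Res = sqrt((4/d) * m2)` (d = 2 for
#' slice ROIs), calibrated so a Gaussian of standard deviation sigma has
#' `Res = 2*sigma`; the real-space PSF width then follows from Gaussian
#' Fourier reciprocity as `Res_real = 2 / (pi * Res_freq)`.
#'
#' A Hann window (default) suppresses leakage from residual large-scale
#' structure; its own spectral broadening is removed by subtracting the
#' window's second moment from the measurement (documented bandwidth
#' correction). Results are floored at 1 pixel.
#'
#' @param image Matrix or `recon_volume`.
#' @param flat_rects List of congruent flat ROIs (4 or more recommended).
#' @param window `"hann"` (default) or `"none"`.
#' @param pixel_size_m Optional pixel pitch to also report meters.
#' @return List of class `"resolution_result"`: `res_px`, `res_m`,
#'   `mtf_width` (cycles/px), `mtf_profile`, `dimension`, `leakage`.
#' @export
resolution_from_noise <- function(image, flat_rects, window = "hann",
                                  pixel_size_m = NULL) {
  .stop_if(length(flat_rects) < 1, "at least one flat ROI is required")
  sp <- .flat_spectra(image, flat_rects, window = window, power = FALSE)
  d <- sp$dims
  spec <- sp$spec
  f1 <- fft_freq(d[1]); f2 <- fft_freq(d[2])
  fr2 <- outer(f1^2, f2^2, `+`)
  spec_m <- spec; spec_m[1, 1] <- 0            # DC excluded from moments
  tot <- sum(spec_m)
  .stop_if(tot == 0, "flat ROIs carry no fluctuation: resolution undefined")
  # DC leakage diagnostic: energy in the lowest non-zero frequency ring
  ring1 <- fr2 > 0 & fr2 <= (1.5 / d[1])^2
  leakage <- sum(spec_m[ring1]) / tot
  if (leakage > 0.5)
    warning("flat ROI spectrum dominated by low-frequency structure; ",
            "region may not be flat")
  m2 <- sum(fr2 * spec_m) / tot
  # bandwidth correction: the window's power spectrum convolves the true one;
  # on the magnitude spectrum this adds twice the window's power-spectral
  # second moment
  if (!identical(window, "none")) {
    wspec <- Mod(fft2(sp$window))^2
    m2w <- sum(fr2 * wspec) / sum(wspec)
    m2 <- max(m2 - 2 * m2w, 1e-12)
  }
  res_f <- sqrt(2 * m2)                        # 4/d with d = 2
  res_px <- max(2 / (pi * res_f), 1)
  structure(list(res_px = res_px,
                 res_m = if (is.null(pixel_size_m)) NULL else res_px * pixel_size_m,
                 mtf_width = res_f,
                 mtf_profile = .radial_profile(spec),
                 dimension = 2L, leakage = leakage),
            class = "resolution_result")
}

#' Intrinsic imaging quality
#'
#' `SNR / Res^(3/2)`, the dose-stripped proxy of the intrinsic quality
#' characteristic `Qs = SNR / (Res^(3/2) * sqrt(D))`, which is proportional to
#' the Shannon information extracted per detected photon. For a fixed-dose
#' comparison the dose factor is a common constant and only the ratio is
#' reported; supplying `dose_mGy` also returns Qs.
#'
#' @param snr Signal-to-noise ratio.
#' @param res Spatial resolution (pixels; use consistent units across a
#'   comparison).
#' @param dose_mGy Optional mean glandular dose (mGy).
#' @return List with `snr_over_res15` and, when dose is given, `qs`.
#' @export
intrinsic_quality <- function(snr, res, dose_mGy = NULL) {
  .stop_if(res <= 0, "'res' must be positive")
  out <- list(snr_over_res15 = snr / res^1.5)
  if (!is.null(dose_mGy)) {
    .stop_if(dose_mGy <= 0, "'dose_mGy' must be positive")
    out$qs <- out$snr_over_res15 / sqrt(dose_mGy)
    out$dose_mGy <- dose_mGy
  }
  out
}

#' Full objective quality bundle for one reconstruction
#'
#' Measures contrast, SNR, CNR (= C x SNR), noise-based spatial resolution
#' and the intrinsic-quality proxy SNR/Res^1.5 on one slice.
#'
#' @param image Matrix or `recon_volume`.
#' @param boundary_rect Boundary ROI for contrast.
#' @param flat_rect Flat ROI (adjacent to the boundary ROI) for the SNR
#'   entering CNR.
#' @param resolution_rects List of flat ROIs for the resolution/NPS estimate;
#'   defaults to `list(flat_rect)`.
#' @param voxel_size_m Pixel pitch for reporting resolution in meters.
#' @param dose_mGy Optional dose for Qs.
#' @return An object of class `"metric_bundle"`.
#' @export
measure_metrics <- function(image, boundary_rect, flat_rect,
                            resolution_rects = NULL, voxel_size_m = NULL,
                            dose_mGy = NULL) {
  if (is.null(voxel_size_m) && inherits(image, "recon_volume"))
    voxel_size_m <- image$voxel_size_m
  if (is.null(resolution_rects)) resolution_rects <- list(flat_rect)
  cn <- measure_cnr(image, boundary_rect, flat_rect)
  rs <- resolution_from_noise(image, resolution_rects,
                              pixel_size_m = voxel_size_m)
  iq <- intrinsic_quality(cn$snr$snr, rs$res_px, dose_mGy)
  structure(list(C = cn$contrast$C, SNR = cn$snr$snr, CNR = cn$cnr,
                 Res_px = rs$res_px, Res_m = rs$res_m,
                 snr_over_res15 = iq$snr_over_res15,
                 qs = iq$qs, dose_mGy = dose_mGy,
                 details = list(contrast = cn$contrast, snr = cn$snr,
                                resolution = rs)),
            class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat("objective image-quality bundle\n")
  cat(sprintf("  contrast C        %.4f\n", x$C))
  cat(sprintf("  SNR               %.3f\n", x$SNR))
  cat(sprintf("  CNR               %.3f\n", x$CNR))
  cat(sprintf("  resolution        %.2f px%s\n", x$Res_px,
              if (is.null(x$Res_m)) "" else sprintf(" (%.0f um)", x$Res_m * 1e6)))
  cat(sprintf("  SNR/Res^1.5       %.3f\n", x$snr_over_res15))
  if (!is.null(x$qs)) cat(sprintf("  Qs (D = %g mGy)    %.3f\n", x$dose_mGy, x$qs))
  invisible(x)
}
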