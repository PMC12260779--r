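#' X-ray wavelength from photon energy
#'
#' Converts a photon energy in keV to the corresponding wavelength in meters
#' using `lambda = hc / E` with `hc = 12.3984` keV·Å. At the 32 keV used for
#' synchrotron breast CT this gives 0.3875 Å.
#'
#' @param energy_keV Photon energy in keV (positive scalar).
#' @return Wavelength in meters.
#' @examples
#' wavelength_from_energy(32) # 3.875e-11 m
#' @export
wavelength_from_energy <- function(energy_keV) {
  .stop_if(!is.numeric(energy_keV) || any(!is.finite(energy_keV)) ||
             any(energy_keV <= 0),
           "'energy_keV' must be a positive finite number")
  (.hc_keV_angstrom / energy_keV) * 1e-10
}

#' Effective propagation distance for a divergent beam
#'
#' For source-to-sample distance R1 and sample-to-detector distance R2 the
#' free-space propagation acts over the effective distance
#' `R' = R1 * R2 / (R1 + R2)`; for a quasi-plane synchrotron beam R' is only
#' slightly smaller than R2 (143 m source and 6 m gap give 5.75 m).
#'
#' @param source_to_detector_m Source-to-detector distance in meters.
#' @param sample_to_detector_m Sample-to-detector (free-space) distance in
#'   meters; must be smaller than `source_to_detector_m`.
#' @return Effective propagation distance in meters (never exceeds
#'   `sample_to_detector_m`).
#' @examples
#' effective_propagation_distance(143, 6) # 5.748 m
#' @export
effective_propagation_distance <- function(source_to_detector_m,
                                           sample_to_detector_m) {
  .stop_if(!is.numeric(source_to_detector_m) || !is.numeric(sample_to_detector_m),
           "distances must be numeric")
  .stop_if(any(sample_to_detector_m < 0) ||
             any(sample_to_detector_m >= source_to_detector_m),
           "need 0 <= sample_to_detector_m < source_to_detector_m")
  r1 <- source_to_detector_m - sample_to_detector_m
  r2 <- sample_to_detector_m
  r1 * r2 / (r1 + r2)
}

#' Acquisition geometry for a parallel-beam PB-CT scan
#'
#' Bundles the beam, distances, detector and angular sampling of a
#' propagation-based CT acquisition. The wavelength is derived from the energy;
#' `system_resolution_m` is the full width `2*sigma_sys` of the combined
#' source/detector blur and is only needed by [fresnel_number()].
#'
#' @param energy_keV Photon energy (keV); default 32.
#' @param source_to_detector_m,sample_to_detector_m Distances in meters
#'   (defaults 143 and 6, a long synchrotron beamline with a 6 m air gap).
#' @param pixel_size_m Detector pixel pitch in meters (default 1e-4, i.e.
#'   0.1 mm).
#' @param angles_deg Ordered projection angles in degrees, strictly increasing
#'   within \[0, 180).
#' @param system_resolution_m Optional full width `2*sigma_sys` of the system
#'   blur (m); about 150 µm for the flat-panel detectors this emulates.
#' @param vertical_profile_sigma_m Optional Gaussian roll-off sigma of the beam
#'   in the vertical direction (m); ~1 cm at the emulated beamline.
#' @return An object of class `"scan_geometry"`.
#' @examples
#' g <- scan_geometry(angles_deg = seq(0, 179.85, by = 0.15))
#' g$effective_distance_m
#' @export
scan_geometry <- function(energy_keV = 32,
                          source_to_detector_m = 143,
                          sample_to_detector_m = 6,
                          pixel_size_m = 1e-4,
                          angles_deg = seq(0, 179.85, by = 0.15),
                          system_resolution_m = 150e-6,
                          vertical_profile_sigma_m = NULL) {
  .stop_if(length(angles_deg) < 1, "at least one projection angle is required")
  .stop_if(any(angles_deg < 0) || any(angles_deg >= 180),
           "angles must lie within [0, 180) degrees")
  .stop_if(length(angles_deg) > 1 && any(diff(angles_deg) <= 0),
           "angles must be strictly increasing")
  .stop_if(pixel_size_m <= 0, "'pixel_size_m' must be positive")
  lambda <- wavelength_from_energy(energy_keV)
  g <- structure(list(
    energy_keV = energy_keV,
    wavelength_m = lambda,
    source_to_detector_m = source_to_detector_m,
    sample_to_detector_m = sample_to_detector_m,
    effective_distance_m = effective_propagation_distance(
      source_to_detector_m, sample_to_detector_m),
    pixel_size_m = pixel_size_m,
    angles_deg = angles_deg,
    system_resolution_m = system_resolution_m,
    vertical_profile_sigma_m = vertical_profile_sigma_m
  ), class = "scan_geometry")
  g
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("PB-CT scan geometry\n")
  cat(sprintf("  energy: %g keV (lambda = %.4g A)\n", x$energy_keV,
              x$wavelength_m * 1e10))
  cat(sprintf("  source-detector %g m, sample-detector %g m (R' = %.3f m)\n",
              x$source_to_detector_m, x$sample_to_detector_m,
              x$effective_distance_m))
  cat(sprintf("  detector pitch %g um, %d angles over [%g, %g] deg\n",
              x$pixel_size_m * 1e6, length(x$angles_deg),
              min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' Width of the first Fresnel fringe
#'
#' `sqrt(R' * lambda)`: the transverse scale of the first free-space
#' interference fringe at a sample edge. For R' = 5.75 m and 0.3875 Å this is
#' about 15 µm, well below the ~150 µm system resolution — the near-Fresnel
#' regime in which most biomedical in-line phase contrast imaging operates.
#'
#' @param geometry A [scan_geometry()].
#' @return Fringe width in meters.
#' @export
fresnel_fringe_width <- function(geometry) {
  .stop_if(!inherits(geometry, "scan_geometry"), "'geometry' must be a scan_geometry")
  sqrt(geometry$effective_distance_m * geometry$wavelength_m)
}

#' Fresnel number of the imaging system
#'
#' `N_F = 2 * pi * sigma_sys^2 / (R' * lambda)` with `sigma_sys` half of the
#' system resolution (full width `2*sigma_sys`). Values well above 1 indicate
#' the near-Fresnel regime; phase contrast remains detectable when the
#' interface phase step is large compared to N_F.
#'
#' @inheritParams fresnel_fringe_width
#' @return Dimensionless Fresnel number.
#' @export
fresnel_number <- function(geometry) {
  .stop_if(!inherits(geometry, "scan_geometry"), "'geometry' must be a scan_geometry")
  .stop_if(is.null(geometry$system_resolution_m),
           "geometry has no 'system_resolution_m'; the Fresnel number needs the system blur")
  sigma_sys <- geometry$system_resolution_m / 2
  2 * pi * sigma_sys^2 / (geometry$effective_distance_m * geometry$wavelength_m)
}

#' In-line phase contrast estimate
#'
#' First-order estimate of the propagation-based contrast of an interface with
#' phase step `delta_phi`: `C = 0.25 * delta_phi / N_F`.
#'
#' @param delta_phi Phase step across the interface in radians.
#' @param fresnel_number Fresnel number of the system (positive).
#' @return Dimensionless contrast estimate.
#' @export
inline_contrast_estimate <- function(delta_phi, fresnel_number) {
  .stop_if(!is.numeric(fresnel_number) || any(fresnel_number <= 0),
           "'fresnel_number' must be positive")
  0.25 * delta_phi / fresnel_number
}
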