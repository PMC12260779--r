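# Persistence: directories of TIFF frames with a JSON sidecar carrying the
# acquisition geometry and provenance. Counts/flats/darks are stored as
# 16-bit TIFF (exact for integer counts up to 65535); reconstructions as
# 32-bit float TIFF.

#' Save a projection set as TIFF frames + JSON sidecar
#'
#' @param pset A [simulate_projections()] result with integer counts.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_projection_set <- function(pset, dir) {
  .stop_if(!inherits(pset, "projection_set"), "'pset' must be a projection_set")
  mx <- max(pset$counts, pset$flats, pset$darks)
  .stop_if(mx > 65535, "counts exceed the 16-bit TIFF range")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(stack, prefix) {
    n <- dim(stack)[1]
    for (i in seq_len(n)) {
      fr <- matrix(stack[i, , ], dim(stack)[2], dim(stack)[3])
      tiff::writeTIFF(t(fr) / 65535, file.path(dir, sprintf("%s_%05d.tif", prefix, i)),
                      bits.per.sample = 16)
    }
    n
  }
  n_ang <- wr(pset$counts, "proj")
  n_fl <- wr(pset$flats, "flat")
  n_dk <- wr(pset$darks, "dark")
  g <- pset$geometry
  side <- list(
    frames = list(projections = n_ang, flats = n_fl, darks = n_dk),
    shape = dim(pset$counts)[2:3],
    geometry = list(energy_keV = g$energy_keV,
                    source_to_detector_m = g$source_to_detector_m,
                    sample_to_detector_m = g$sample_to_detector_m,
                    pixel_size_m = g$pixel_size_m,
                    angles_deg = g$angles_deg,
                    system_resolution_m = g$system_resolution_m,
                    vertical_profile_sigma_m = g$vertical_profile_sigma_m),
    fluence_per_projection = pset$fluence_per_projection,
    propagation_model = pset$propagation_model,
    gamma_true = pset$gamma_true, noise = pset$noise,
    dark_offset = pset$dark_offset, seed = pset$seed)
  jsonlite::write_json(side, file.path(dir, "scan.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Load a projection set saved by [write_projection_set()]
#'
#' @param dir Directory containing the TIFF frames and `scan.json`.
#' @return A `"projection_set"`.
#' @export
read_projection_set <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "scan.json"), simplifyVector = TRUE)
  shp <- as.integer(side$shape)
  rd <- function(prefix, n) {
    out <- array(0, dim = c(n, shp[1], shp[2]))
    for (i in seq_len(n)) {
      fr <- tiff::readTIFF(file.path(dir, sprintf("%s_%05d.tif", prefix, i)))
      out[i, , ] <- round(t(fr * 65535))
    }
    out
  }
  g <- side$geometry
  geometry <- scan_geometry(energy_keV = g$energy_keV,
                            source_to_detector_m = g$source_to_detector_m,
                            sample_to_detector_m = g$sample_to_detector_m,
                            pixel_size_m = g$pixel_size_m,
                            angles_deg = g$angles_deg,
                            system_resolution_m = g$system_resolution_m,
                            vertical_profile_sigma_m = g$vertical_profile_sigma_m)
  structure(list(counts = rd("proj", side$frames$projections),
                 flats = rd("flat", side$frames$flats),
                 darks = rd("dark", side$frames$darks),
                 geometry = geometry,
                 fluence_per_projection = side$fluence_per_projection,
                 propagation_model = side$propagation_model,
                 gamma_true = side$gamma_true, noise = side$noise,
                 seed = side$seed, dark_offset = side$dark_offset,
                 clipped = NA_integer_),
            class = "projection_set")
}

#' Save a reconstruction as 32-bit float TIFF + JSON sidecar
#'
#' @param vol A `recon_volume`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_recon_volume <- function(vol, dir) {
  .stop_if(!inherits(vol, "recon_volume"), "'vol' must be a recon_volume")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  b <- vol$beta
  if (length(dim(b)) == 2) b <- array(b, dim = c(dim(b), 1))
  for (z in seq_len(dim(b)[3]))
    tiff::writeTIFF(t(b[, , z]), file.path(dir, sprintf("slice_%04d.tif", z)),
                    bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(algorithm = vol$algorithm,
                            voxel_size_m = vol$voxel_size_m,
                            n_slices = dim(b)[3],
                            params_used = vol$params_used),
                       file.path(dir, "recon.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(dir)
}
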