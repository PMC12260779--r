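# Minimal DICOM Part-10 writer/reader (explicit VR, little endian) for the
# 12-bit thick-slice export. Only the small tag set needed for PACS-style
# viewing of a CT series is written; the reader understands exactly what the
# writer emits (plus any explicit-VR elements it skips), which is enough for
# the bit-exact round-trip contract.

.dcm_uid_root <- "1.2.826.0.1.3680043.10.1474."

.dcm_pad <- function(raw, pad = as.raw(0x20)) {
  if (length(raw) %% 2 == 1) c(raw, pad) else raw
}

.dcm_uint <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "little")
}

.dcm_element <- function(group, element, vr, value_raw) {
  head <- c(.dcm_uint(group, 2), .dcm_uint(element, 2), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), .dcm_uint(length(value_raw), 4), value_raw)
  } else {
    c(head, .dcm_uint(length(value_raw), 2), value_raw)
  }
}

.dcm_str <- function(group, element, vr, value) {
  pad <- if (vr == "UI") as.raw(0) else as.raw(0x20)
  .dcm_element(group, element, vr, .dcm_pad(charToRaw(as.character(value)), pad))
}

.dcm_us <- function(group, element, value) {
  .dcm_element(group, element, "US", .dcm_uint(value, 2))
}

#' Write a thick-slice stack as a DICOM series
#'
#' One explicit-VR little-endian DICOM file per slice (CT Image Storage),
#' 16 bits allocated / 12 stored, MONOCHROME2, with pixel spacing, slice
#' thickness and spacing-between-slices taken from the rebinning geometry.
#' Instance numbers are consecutive and UIDs deterministic (derived from
#' `series_number`), so identical inputs produce identical files.
#'
#' @param slices A [rebin_axial()] result, or a 3D integer array (slice index
#'   last), or a single matrix. Values must fit 12 bits (0..4095).
#' @param dir Output directory (created if needed).
#' @param patient_meta List with at least `patient_name` and `patient_id`;
#'   missing fields raise an error listing them.
#' @param pixel_spacing_mm In-plane pixel size (mm); taken from the
#'   `thick_slices` record when available.
#' @param slice_thickness_mm,spacing_between_mm Thick-slice geometry (mm);
#'   derived from the `thick_slices` record when available.
#' @param series_number Integer used to derive the deterministic UIDs.
#' @return Invisibly, the vector of file paths written (one per slice,
#'   consecutive instance numbers).
#' @export
write_dicom_series <- function(slices, dir, patient_meta,
                               pixel_spacing_mm = NULL,
                               slice_thickness_mm = NULL,
                               spacing_between_mm = NULL,
                               series_number = 1L) {
  missing_fields <- setdiff(c("patient_name", "patient_id"), names(patient_meta))
  .stop_if(length(missing_fields) > 0,
           "missing mandatory metadata: ", paste(missing_fields, collapse = ", "))
  if (inherits(slices, "thick_slices")) {
    vx <- slices$voxel_size_m
    if (is.null(pixel_spacing_mm) && !is.null(vx)) pixel_spacing_mm <- vx * 1e3
    if (is.null(slice_thickness_mm) && !is.null(vx))
      slice_thickness_mm <- slices$thickness_voxels * vx * 1e3
    if (is.null(spacing_between_mm) && !is.null(vx))
      spacing_between_mm <- slices$spacing_voxels * vx * 1e3
    slices <- slices$slices
  }
  if (is.matrix(slices)) slices <- array(slices, dim = c(dim(slices), 1))
  .stop_if(is.null(pixel_spacing_mm), "'pixel_spacing_mm' is required")
  if (is.null(slice_thickness_mm)) slice_thickness_mm <- 3
  if (is.null(spacing_between_mm)) spacing_between_mm <- 1.5
  .stop_if(any(slices < 0) || any(slices > 4095),
           "pixel values must fit 12 bits (0..4095)")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nsl <- dim(slices)[3]
  study_uid <- paste0(.dcm_uid_root, series_number, ".0")
  series_uid <- paste0(.dcm_uid_root, series_number, ".1")
  paths <- character(nsl)
  for (i in seq_len(nsl)) {
    sop_uid <- paste0(series_uid, ".", i)
    pix <- slices[, , i]
    rows <- nrow(pix); cols <- ncol(pix)
    pix_raw <- writeBin(as.integer(t(pix)), raw(), size = 2, endian = "little")

    ds <- c(
      .dcm_str(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcm_str(0x0008, 0x0018, "UI", sop_uid),
      .dcm_str(0x0008, 0x0060, "CS", "CT"),
      .dcm_str(0x0010, 0x0010, "PN", patient_meta$patient_name),
      .dcm_str(0x0010, 0x0020, "LO", patient_meta$patient_id),
      .dcm_str(0x0018, 0x0050, "DS", format(slice_thickness_mm)),
      .dcm_str(0x0018, 0x0088, "DS", format(spacing_between_mm)),
      .dcm_str(0x0020, 0x000D, "UI", study_uid),
      .dcm_str(0x0020, 0x000E, "UI", series_uid),
      .dcm_str(0x0020, 0x0013, "IS", as.character(i)),
      .dcm_str(0x0020, 0x0032, "DS",
               paste(0, 0, format((i - 1) * spacing_between_mm), sep = "\\")),
      .dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      .dcm_us(0x0028, 0x0002, 1),
      .dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcm_us(0x0028, 0x0010, rows),
      .dcm_us(0x0028, 0x0011, cols),
      .dcm_str(0x0028, 0x0030, "DS",
               paste(format(pixel_spacing_mm), format(pixel_spacing_mm),
                     sep = "\\")),
      .dcm_us(0x0028, 0x0100, 16),
      .dcm_us(0x0028, 0x0101, 12),
      .dcm_us(0x0028, 0x0102, 11),
      .dcm_us(0x0028, 0x0103, 0),
      .dcm_element(0x7FE0, 0x0010, "OW", pix_raw)
    )
    meta_body <- c(
      .dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcm_str(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcm_str(0x0002, 0x0003, "UI", sop_uid),
      .dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
      .dcm_str(0x0002, 0x0012, "UI", paste0(.dcm_uid_root, "0.1"))
    )
    meta <- c(.dcm_element(0x0002, 0x0000, "UL", .dcm_uint(length(meta_body), 4)),
              meta_body)
    paths[i] <- file.path(dir, sprintf("slice_%04d.dcm", i))
    con <- file(paths[i], "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, ds), con)
    close(con)
  }
  invisible(paths)
}

#' Read one DICOM slice written by [write_dicom_series()]
#'
#' A minimal explicit-VR little-endian parser: collects string/US elements
#' into a tag table and decodes the 16-bit pixel data.
#'
#' @param path Path to a `.dcm` file.
#' @return List with `tags` (named list, names `"gggg,eeee"`), `pixel`
#'   (integer matrix), `rows`, `cols`.
#' @export
read_dicom_slice <- function(path) {
  raw <- readBin(path, raw(), file.size(path))
  .stop_if(length(raw) < 140 || rawToChar(raw[129:132]) != "DICM",
           "not a DICOM Part-10 file")
  pos <- 133L
  tags <- list()
  pixel <- NULL
  rows <- cols <- NA_integer_
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) u16(at) + 65536 * u16(at + 2L)
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      val_at <- pos + 8L
    }
    val <- if (len > 0) raw[val_at:(val_at + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", group, element)
    if (group == 0x7FE0 && element == 0x0010) {
      pixel <- readBin(val, integer(), n = len %/% 2, size = 2,
                       endian = "little")
    } else if (vr == "US") {
      v <- u16(val_at)
      tags[[key]] <- v
      if (group == 0x0028 && element == 0x0010) rows <- v
      if (group == 0x0028 && element == 0x0011) cols <- v
    } else if (vr %in% c("UI", "CS", "DS", "IS", "PN", "LO", "DA", "SH", "LT")) {
      tags[[key]] <- sub(" +$", "", rawToChar(val[val != as.raw(0)]))
    }
    pos <- val_at + len
  }
  .stop_if(is.null(pixel) || is.na(rows) || is.na(cols),
           "file has no decodable pixel data")
  list(tags = tags, pixel = matrix(pixel, nrow = rows, ncol = cols, byrow = TRUE),
       rows = rows, cols = cols)
}
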