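#' Stitch vertically overlapping reconstruction slabs
#'
#' Consecutive slabs (acquired with the sample translated vertically, e.g.
#' 2.5 cm slabs overlapping by 1 cm) are merged along the slice-stack axis.
#' Overlap regions are blended with a linear ramp by default (`"ramp"`), or
#' cut at the overlap midline (`"cut"`); non-overlapping regions are copied
#' verbatim. The output height is `sum(heights) - (n-1) * overlap`.
#'
#' @param slabs List of `recon_volume`s or 3D arrays with congruent
#'   transverse shapes.
#' @param overlap_voxels Overlap along the stack axis (voxels), smaller than
#'   every slab height.
#' @param method `"ramp"` (linear cross-fade) or `"cut"`.
#' @return A `recon_volume` (or bare array if bare arrays were supplied).
#' @export
stitch_slabs <- function(slabs, overlap_voxels, method = c("ramp", "cut")) {
  method <- match.arg(method)
  .stop_if(length(slabs) < 1, "need at least one slab")
  arrs <- lapply(slabs, function(s) if (inherits(s, "recon_volume")) s$beta else s)
  arrs <- lapply(arrs, function(a) {
    if (length(dim(a)) == 2) array(a, dim = c(dim(a), 1)) else a
  })
  d1 <- dim(arrs[[1]])
  for (a in arrs)
    .stop_if(!all(dim(a)[1:2] == d1[1:2]), "slabs have inconsistent transverse shapes")
  ov <- as.integer(overlap_voxels)
  heights <- vapply(arrs, function(a) dim(a)[3], integer(1))
  .stop_if(length(arrs) > 1 && (ov < 0 || any(ov >= heights)),
           "'overlap_voxels' must be smaller than every slab height")
  out <- arrs[[1]]
  if (length(arrs) > 1) {
    for (i in 2:length(arrs)) {
      nxt <- arrs[[i]]
      if (ov == 0) {
        out <- .abind3(out, nxt)
        next
      }
      ho <- dim(out)[3]
      top <- out[, , ho - ov + seq_len(ov), drop = FALSE]
      bot <- nxt[, , seq_len(ov), drop = FALSE]
      blend <- array(0, dim = c(d1[1], d1[2], ov))
      if (method == "ramp") {
        wt <- (seq_len(ov) - 0.5) / ov      # weight of the incoming slab
        for (k in seq_len(ov))
          blend[, , k] <- (1 - wt[k]) * top[, , k] + wt[k] * bot[, , k]
      } else {
        half <- ov %/% 2
        for (k in seq_len(ov))
          blend[, , k] <- if (k <= half) top[, , k] else bot[, , k]
      }
      out <- .abind3(out[, , seq_len(ho - ov), drop = FALSE], blend,
                     nxt[, , ov + seq_len(dim(nxt)[3] - ov), drop = FALSE])
    }
  }
  if (inherits(slabs[[1]], "recon_volume"))
    .recon_volume(out, slabs[[1]]$voxel_size_m, slabs[[1]]$algorithm,
                  c(slabs[[1]]$params_used,
                    list(stitched = length(slabs), overlap_voxels = ov,
                         stitch_method = method)))
  else out
}

.abind3 <- function(...) {
  pieces <- list(...)
  d <- dim(pieces[[1]])
  nz <- sum(vapply(pieces, function(p) dim(p)[3], integer(1)))
  out <- array(0, dim = c(d[1], d[2], nz))
  at <- 0L
  for (p in pieces) {
    k <- dim(p)[3]
    out[, , at + seq_len(k)] <- p
    at <- at + k
  }
  out
}

#' Rebinning parameters for thick-slice generation
#'
#' @param bin_size Voxels averaged per output slice along the rebin axis
#'   (default 30: 3 mm at 0.1 mm voxels).
#' @param step Voxels between consecutive output slices (default 15, i.e. a
#'   50% overlap that reduces apparent jumps between consecutive thick
#'   slices).
#' @param beta_thresh Calcification threshold separating soft tissue from
#'   calcifications (default 2e-10).
#' @return An object of class `"rebin_params"`.
#' @export
rebin_params <- function(bin_size = 30L, step = 15L, beta_thresh = 2e-10) {
  .stop_if(step < 1 || step > bin_size, "need 1 <= step <= bin_size")
  structure(list(bin_size = as.integer(bin_size), step = as.integer(step),
                 beta_thresh = beta_thresh),
            class = "rebin_params")
}

#' Calcification-preserving thick-slice rebinning
#'
#' Reorients the reconstruction so `axis` becomes the through-plane direction
#' and collapses each column of `bin_size` voxels into one thick-slice value:
#' the column is split at `beta_thresh` into a lower (soft tissue) and an
#' upper (calcification) bin; if the upper bin is non-empty its mean is the
#' output (so micro-calcifications are never washed out by the averaging),
#' otherwise the lower-bin mean is a denoised soft-tissue value.
#'
#' @param volume A `recon_volume` with a 3D beta grid, or a 3D array.
#' @param params A [rebin_params()].
#' @param axis Axis (1, 2 or 3) to rebin along; default 3 assumes the volume
#'   is already oriented with the target through-plane direction last (use
#'   `aperm()` or `axis` for the coronal-to-axial reorientation, a pure axis
#'   permutation).
#' @return List of class `"thick_slices"`: `slices` (3D array, thick-slice
#'   index last), `thickness_voxels`, `spacing_voxels`, `beta_thresh`,
#'   `voxel_size_m` (when known).
#' @export
rebin_axial <- function(volume, params = rebin_params(), axis = 3L) {
  .stop_if(!inherits(params, "rebin_params"), "'params' must be rebin_params")
  vx <- if (inherits(volume, "recon_volume")) volume$voxel_size_m else NULL
  a <- if (inherits(volume, "recon_volume")) volume$beta else volume
  .stop_if(length(dim(a)) != 3, "rebinning needs a 3D volume")
  if (axis != 3) a <- aperm(a, c(setdiff(1:3, axis), axis))
  d <- dim(a)
  H <- d[3]
  .stop_if(H < params$bin_size, "volume height is smaller than the bin size")
  nsl <- (H - params$bin_size) %/% params$step + 1L
  out <- array(0, dim = c(d[1], d[2], nsl))
  npx <- d[1] * d[2]
  for (i in seq_len(nsl)) {
    i0 <- (i - 1L) * params$step
    m <- matrix(a[, , i0 + seq_len(params$bin_size)], npx, params$bin_size)
    up <- m > params$beta_thresh
    n_up <- rowSums(up)
    sum_up <- rowSums(m * up)
    val <- ifelse(n_up > 0, sum_up / n_up,
                  (rowSums(m) - sum_up) / (params$bin_size - n_up))
    out[, , i] <- val
  }
  structure(list(slices = out, thickness_voxels = params$bin_size,
                 spacing_voxels = params$step, beta_thresh = params$beta_thresh,
                 voxel_size_m = vx),
            class = "thick_slices")
}

#' 12-bit linear display mapping
#'
#' @param beta_in_min,beta_in_max Input clipping range; the defaults 5e-11
#'   and 7e-10 bracket soft breast tissue from below and calcifications from
#'   above at 32 keV, so clipping loses no anatomically meaningful values.
#' @param i_out_min,i_out_max Output integer range (default 0..4095 = 2^12-1).
#' @param rounding Rounding policy; `"half-up"` (default) or `"nearest-even"`.
#' @return An object of class `"twelve_bit_mapping"`.
#' @export
twelve_bit_mapping <- function(beta_in_min = 5e-11, beta_in_max = 7e-10,
                               i_out_min = 0L, i_out_max = 4095L,
                               rounding = c("half-up", "nearest-even")) {
  rounding <- match.arg(rounding)
  .stop_if(beta_in_min >= beta_in_max, "need beta_in_min < beta_in_max")
  structure(list(beta_in_min = beta_in_min, beta_in_max = beta_in_max,
                 i_out_min = as.integer(i_out_min),
                 i_out_max = as.integer(i_out_max), rounding = rounding),
            class = "twelve_bit_mapping")
}

#' Map beta values to 12-bit integers
#'
#' Clips to `[beta_in_min, beta_in_max]`, maps linearly onto
#' `[i_out_min, i_out_max]` and rounds (half-up by default). Monotone by
#' construction.
#'
#' @param volume Numeric array/matrix of beta values (or `thick_slices`).
#' @param mapping A [twelve_bit_mapping()].
#' @return Integer array of the same shape.
#' @export
map_to_12bit <- function(volume, mapping = twelve_bit_mapping()) {
  .stop_if(!inherits(mapping, "twelve_bit_mapping"),
           "'mapping' must be a twelve_bit_mapping")
  x <- if (inherits(volume, "thick_slices")) volume$slices else volume
  nbad <- sum(!is.finite(x))
  .stop_if(nbad > 0, sprintf("%d non-finite input values", nbad))
  d <- dim(x)
  x <- pmin(pmax(x, mapping$beta_in_min), mapping$beta_in_max)
  y <- mapping$i_out_min + (mapping$i_out_max - mapping$i_out_min) *
    (x - mapping$beta_in_min) / (mapping$beta_in_max - mapping$beta_in_min)
  out <- if (mapping$rounding == "half-up") as.integer(floor(y + 0.5))
         else as.integer(round(y))
  dim(out) <- d
  out
}
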