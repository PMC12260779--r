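# Soft-tissue beta values must stay inside these bounds at 32 keV: the 12-bit
# display mapping assumes soft tissue in [5e-11, 7e-10] and the rebinning
# threshold 2e-10 separates soft tissue (below) from calcifications (above).
.beta_soft_min <- 5e-11
.beta_soft_max <- 7e-10
.beta_calc_thresh <- 2e-10

#' Phantom specification for a breast-like test object
#'
#' Describes a cylindrical sample container filled with tissue primitives.
#' Geometry is given in meters relative to the volume center; the container
#' axis is the z (slice-stack) axis. Primitives are rasterized in order, later
#' entries overriding earlier ones.
#'
#' Supported primitive `type`s: `"cylinder"` (fields `center` = c(x, y),
#' `radius`, optional `zmin`/`zmax`), `"sphere"` (`center` = c(x, y, z),
#' `radius`), `"ellipsoid"` (`center`, `semiaxes` = c(ax, ay, az)) and
#' `"box"` (`center`, `half` = c(hx, hy, hz)).
#'
#' @param container_diameter_m Inner diameter of the sample container (m).
#' @param grid_shape Integer vector `c(nx, ny, nz)` of voxel counts.
#' @param voxel_size_m Isotropic voxel pitch (m).
#' @param tissue_components List of primitives, each a list with fields
#'   `label`, `type`, geometry fields, and `beta` (soft tissue: must lie in
#'   \[5e-11, 2e-10)).
#' @param calcifications List of `list(center, radius, beta)` spheres with
#'   `beta` above the 2e-10 calcification threshold.
#' @param gamma_true True delta/beta ratio of the (quasi-homogeneous) tissue,
#'   used by the propagation forward models; default 550, twice the
#'   "half retrieval" filter setting of 275.
#' @param seed Integer seed recorded with the spec (used by generators that
#'   place primitives randomly).
#' @return An object of class `"phantom_spec"`.
#' @seealso [breast_phantom_spec()] for a ready-made breast-like default,
#'   [make_phantom()] to rasterize.
#' @export
phantom_spec <- function(container_diameter_m,
                         grid_shape,
                         voxel_size_m = 1e-4,
                         tissue_components = list(),
                         calcifications = list(),
                         gamma_true = 550,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  .stop_if(length(grid_shape) != 3 || any(grid_shape < 1),
           "'grid_shape' must be three positive integers (nx, ny, nz)")
  .stop_if(voxel_size_m <= 0, "'voxel_size_m' must be positive")
  .stop_if(container_diameter_m <= 0, "'container_diameter_m' must be positive")
  for (tc in tissue_components) {
    .stop_if(is.null(tc$beta) || tc$beta < .beta_soft_min ||
               tc$beta >= .beta_calc_thresh,
             "soft-tissue beta values must lie in [5e-11, 2e-10)")
  }
  for (cc in calcifications) {
    .stop_if(is.null(cc$beta) || cc$beta <= .beta_calc_thresh,
             "calcification beta must exceed 2e-10")
  }
  structure(list(container_diameter_m = container_diameter_m,
                 grid_shape = grid_shape,
                 voxel_size_m = voxel_size_m,
                 tissue_components = tissue_components,
                 calcifications = calcifications,
                 gamma_true = gamma_true,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Breast-like phantom specification
#'
#' Builds a [phantom_spec()] emulating the imaging study's samples: an
#' adipose-filled cylindrical container holding one large glandular mass with
#' a well-defined straight-ish interface (convenient for contrast ROIs),
#' optional additional glandular blobs placed with the seeded RNG, and a
#' cluster of micro-calcifications inside the mass.
#'
#' At full experimental scale the container is 11 cm across with 0.1 mm
#' voxels (1100 voxels); for desk-scale work pass a smaller `grid_shape` and
#' the container shrinks to 88% of the field of view unless given explicitly.
#'
#' Default beta values at 32 keV (configuration choices inside the documented
#' soft-tissue/calcification bounds, not physics claims): adipose 1.2e-10,
#' glandular 1.6e-10, calcification 5e-10.
#'
#' @param grid_shape Voxel counts `c(nx, ny, nz)`; default desk scale
#'   `c(128, 128, 1)`.
#' @param voxel_size_m Voxel pitch (m), default 1e-4.
#' @param container_diameter_m Container diameter (m); `NULL` means 88% of the
#'   transverse field of view.
#' @param beta_adipose,beta_glandular,beta_calc Component beta values.
#' @param n_extra_glands Number of additional randomly placed glandular blobs.
#' @param n_calcs Number of micro-calcifications in the cluster (0 disables).
#' @param calc_radius_m Radius of each micro-calcification (m).
#' @param gamma_true True delta/beta ratio; default 550.
#' @param seed RNG seed for the random placements.
#' @return A `"phantom_spec"`.
#' @export
breast_phantom_spec <- function(grid_shape = c(128, 128, 1),
                                voxel_size_m = 1e-4,
                                container_diameter_m = NULL,
                                beta_adipose = 1.2e-10,
                                beta_glandular = 1.6e-10,
                                beta_calc = 5e-10,
                                n_extra_glands = 3,
                                n_calcs = 4,
                                calc_radius_m = 2 * voxel_size_m,
                                gamma_true = 550,
                                seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  fov <- min(grid_shape[1], grid_shape[2]) * voxel_size_m
  if (is.null(container_diameter_m)) container_diameter_m <- 0.88 * fov
  R <- container_diameter_m / 2
  zh <- grid_shape[3] * voxel_size_m / 2
  comps <- list(
    list(label = "adipose", type = "cylinder", center = c(0, 0),
         radius = R, beta = beta_adipose),
    # main glandular mass: offset ellipsoid leaving a broad adipose region
    # above and to its left, giving clean interfaces for contrast/CNR ROIs
    list(label = "glandular", type = "ellipsoid",
         center = c(0.3 * R, 0.3 * R, 0),
         semiaxes = c(0.45 * R, 0.45 * R, max(zh, voxel_size_m)),
         beta = beta_glandular)
  )
  set.seed(seed)
  if (n_extra_glands > 0) {
    for (i in seq_len(n_extra_glands)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0.45, 0.75) * R
      a <- runif(1, 0.06, 0.14) * R
      comps[[length(comps) + 1]] <- list(
        label = "glandular", type = "ellipsoid",
        center = c(rad * cos(ang), rad * sin(ang), 0),
        semiaxes = c(a, a * runif(1, 0.7, 1.3), max(zh, voxel_size_m)),
        beta = beta_glandular)
    }
  }
  calcs <- list()
  if (n_calcs > 0) {
    cl_center <- c(0.3 * R, 0.3 * R)
    for (i in seq_len(n_calcs)) {
      off <- runif(2, -0.08, 0.08) * R
      calcs[[i]] <- list(center = c(cl_center + off, 0),
                        radius = calc_radius_m, beta = beta_calc)
    }
  }
  phantom_spec(container_diameter_m = container_diameter_m,
               grid_shape = grid_shape, voxel_size_m = voxel_size_m,
               tissue_components = comps, calcifications = calcs,
               gamma_true = gamma_true, seed = seed)
}

# voxel-center coordinates (m) along one axis, centered on the volume
.axis_coords <- function(n, voxel) (seq_len(n) - (n + 1) / 2) * voxel

.primitive_mask <- function(prim, xs, ys, zs) {
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  switch(prim$type,
    cylinder = {
      d2 <- outer((xs - prim$center[1])^2, (ys - prim$center[2])^2, `+`)
      m2 <- d2 <= prim$radius^2
      zin <- rep(TRUE, nz)
      if (!is.null(prim$zmin)) zin <- zin & (zs >= prim$zmin)
      if (!is.null(prim$zmax)) zin <- zin & (zs <= prim$zmax)
      outer(m2, zin, `&`)
    },
    sphere = {
      d2 <- outer((xs - prim$center[1])^2, (ys - prim$center[2])^2, `+`)
      outer(d2, (zs - prim$center[3])^2, `+`) <= prim$radius^2
    },
    ellipsoid = {
      d2 <- outer(((xs - prim$center[1]) / prim$semiaxes[1])^2,
                  ((ys - prim$center[2]) / prim$semiaxes[2])^2, `+`)
      outer(d2, ((zs - prim$center[3]) / prim$semiaxes[3])^2, `+`) <= 1
    },
    box = {
      inx <- abs(xs - prim$center[1]) <= prim$half[1]
      iny <- abs(ys - prim$center[2]) <= prim$half[2]
      inz <- abs(zs - prim$center[3]) <= prim$half[3]
      outer(outer(inx, iny, `&`), inz, `&`)
    },
    stop("unknown primitive type: ", prim$type, call. = FALSE)
  )
}

.primitive_fits_container <- function(prim, R, zhalf) {
  ok <- switch(prim$type,
    cylinder = sqrt(sum(prim$center[1:2]^2)) + prim$radius <= R * (1 + 1e-9),
    # z extent is not checked: the volume's z-range simply crops primitives
    sphere = sqrt(sum(prim$center[1:2]^2)) + prim$radius <= R * (1 + 1e-9),
    ellipsoid = sqrt(sum(prim$center[1:2]^2)) +
      max(prim$semiaxes[1:2]) <= R * (1 + 1e-9),
    box = sqrt(sum(prim$center[1:2]^2)) +
      sqrt(sum(prim$half[1:2]^2)) <= R * (1 + 1e-9),
    TRUE)
  isTRUE(ok)
}

#' Rasterize a phantom specification into a voxel volume
#'
#' Produces the simulation ground truth: a 3D grid of the imaginary
#' refractive-index decrement beta plus a congruent integer label grid.
#' Rasterization is deterministic; voxels outside the container carry beta = 0
#' and label `"background"`. Later primitives override earlier ones (the
#' documented layering convention); calcifications are rasterized last.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `"phantom_volume"`: list with `beta` (3D array),
#'   `labels` (3D integer array), `label_names`, `voxel_size_m`, `spec`.
#' @export
make_phantom <- function(spec) {
  .stop_if(!inherits(spec, "phantom_spec"), "'spec' must be a phantom_spec")
  ns <- spec$grid_shape
  vx <- spec$voxel_size_m
  xs <- .axis_coords(ns[1], vx); ys <- .axis_coords(ns[2], vx)
  zs <- .axis_coords(ns[3], vx)
  R <- spec$container_diameter_m / 2
  zhalf <- ns[3] * vx / 2
  beta <- array(0, dim = ns)
  labels <- array(0L, dim = ns)
  label_names <- "background"
  container <- outer(outer(xs^2, ys^2, `+`) <= R^2, rep(TRUE, ns[3]), `&`)
  prims <- spec$tissue_components
  for (cc in spec$calcifications) {
    prims[[length(prims) + 1]] <- list(label = "calcification", type = "sphere",
                                       center = cc$center, radius = cc$radius,
                                       beta = cc$beta)
  }
  for (prim in prims) {
    .stop_if(!.primitive_fits_container(prim, R, zhalf),
             "primitive '", prim$label, "' does not fit inside the container")
    code <- match(prim$label, label_names)
    if (is.na(code)) {
      label_names <- c(label_names, prim$label)
      code <- length(label_names)
    }
    mask <- .primitive_mask(prim, xs, ys, zs) & container
    beta[mask] <- prim$beta
    labels[mask] <- code - 1L
  }
  structure(list(beta = beta, labels = labels, label_names = label_names,
                 voxel_size_m = vx, spec = spec),
            class = "phantom_volume")
}

#' @export
print.phantom_volume <- function(x, ...) {
  ns <- dim(x$beta)
  cat(sprintf("phantom_volume: %d x %d x %d voxels at %g um\n",
              ns[1], ns[2], ns[3], x$voxel_size_m * 1e6))
  tab <- table(factor(x$labels, levels = seq_along(x$label_names) - 1L,
                      labels = x$label_names))
  for (nm in names(tab)) cat(sprintf("  %-14s %d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

#' Parallel-beam line integrals of a phantom volume
#'
#' Forward-projects the beta volume along parallel rays for each angle
#' (Joseph-style ray-driven sampling with bilinear interpolation, one detector
#' column per voxel column). Output units are beta times length (meters).
#'
#' @param volume A [make_phantom()] result (or a 2D/3D numeric array with a
#'   `voxel_size_m` argument).
#' @param angles_deg Projection angles in degrees within \[0, 180).
#' @param voxel_size_m Voxel pitch, required when `volume` is a bare array.
#' @return 3D array `(n_angles, n_det, nz)` of line integrals of beta (m).
#' @export
project_parallel <- function(volume, angles_deg, voxel_size_m = NULL) {
  if (inherits(volume, "phantom_volume")) {
    beta <- volume$beta
    voxel_size_m <- volume$voxel_size_m
  } else {
    beta <- volume
    .stop_if(is.null(voxel_size_m), "'voxel_size_m' required for bare arrays")
  }
  .stop_if(length(angles_deg) < 1, "empty angle list")
  .stop_if(any(angles_deg < 0) || any(angles_deg >= 180),
           "angles must lie within [0, 180)")
  if (length(dim(beta)) == 2) beta <- array(beta, dim = c(dim(beta), 1))
  ns <- dim(beta)
  th <- angles_deg * pi / 180
  out <- array(0, dim = c(length(th), ns[1], ns[3]))
  for (z in seq_len(ns[3])) {
    out[, , z] <- cpp_forward_project(beta[, , z], cos(th), sin(th),
                                      ns[1], 0.5) * voxel_size_m
  }
  out
}
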