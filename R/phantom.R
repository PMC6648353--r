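## Nested-ellipsoid head phantom: a CSF rim enclosing a GM shell enclosing a
## WM core, on a shared voxel grid. Partial volumes come from a one-voxel
## linear anti-aliasing ramp at each class boundary, so pv maps are in [0,1]
## and sum exactly to one with the background.

default_shape_params <- function() {
  list(
    outer_radii_mm = c(70, 75, 65),  # head (outer CSF) semi-axes: x, y, z
    csf_mm         = 5,              # CSF rim thickness
    gm_mm          = 16,             # GM shell thickness
    jitter_sd      = 0.03            # per-axis fractional radius jitter
  )
}

## Smoothed occupancy of an ellipsoid with semi-axes r_mm centred at
## centre_mm: 1 deep inside, 0 outside, linear over ~one voxel at the rim.
ellipsoid_occupancy <- function(grids, extent_mm, centre_frac, r_mm, voxel_mm) {
  dx <- (grids$x - centre_frac[1]) * extent_mm[1]
  dy <- (grids$y - centre_frac[2]) * extent_mm[2]
  dz <- (grids$z - centre_frac[3]) * extent_mm[3]
  rho <- sqrt((dx / r_mm[1])^2 + (dy / r_mm[2])^2 + (dz / r_mm[3])^2)
  rbar <- exp(mean(log(r_mm)))  # geometric-mean radius sets the ramp scale
  pmin(pmax(0.5 + (1 - rho) * rbar / voxel_mm, 0), 1)
}

#' Generate a three-tissue head phantom
#'
#' Builds a nested-ellipsoid "head" (CSF rim, gray-matter shell, white-matter
#' core) with smooth per-subject perturbation of the semi-axes and shell
#' thicknesses. Class boundaries are anti-aliased over one voxel, which is
#' what produces partial-volume voxels.
#'
#' @param grid_shape integer length-3, each entry at least 32.
#' @param voxel_mm isotropic voxel size in mm.
#' @param shape_params list with `outer_radii_mm`, `csf_mm`, `gm_mm`,
#'   `jitter_sd`; see `default_shape_params` for defaults.
#' @param tissue_means noiseless intensity per class,
#'   named `csf`, `gm`, `wm` (arbitrary units, T1-like contrast).
#' @param seed integer controlling the per-subject shape jitter.
#' @return object of class `tissue_phantom`: pv maps (`pv_csf`, `pv_gm`,
#'   `pv_wm`), `tissue_means`, `shape_params` (as realized), `voxel_mm`,
#'   `grid_shape`, `deform_seed`.
#' @examples
#' ph <- make_tissue_phantom(c(32, 32, 32), voxel_mm = 6, seed = 1)
#' range(ph$pv_gm + ph$pv_wm + ph$pv_csf)
#' @export
make_tissue_phantom <- function(grid_shape = c(64, 64, 64), voxel_mm = 3,
                                shape_params = default_shape_params(),
                                tissue_means = c(csf = 0.30, gm = 0.60, wm = 0.90),
                                seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, voxel_mm > 0)
  if (any(grid_shape < 32L))
    stop("grid_shape must be at least 32 voxels per axis")
  sp <- utils::modifyList(default_shape_params(), shape_params)
  extent_mm <- grid_shape * voxel_mm

  real <- with_seed(seed, {
    # truncated at 2.5 SD so jittered heads always fit the field of view
    jit <- function(k) 1 + pmin(pmax(rnorm(k, 0, sp$jitter_sd),
                                     -2.5 * sp$jitter_sd), 2.5 * sp$jitter_sd)
    list(
      outer = sp$outer_radii_mm * jit(3),
      csf   = sp$csf_mm * jit(1),
      gm    = sp$gm_mm * jit(1),
      centre = 0.5 + pmin(pmax(rnorm(3, 0, 0.01), -0.025), 0.025)
    )
  })
  r1 <- real$outer
  r2 <- r1 - real$csf
  r3 <- r2 - real$gm
  if (any(r3 <= 2 * voxel_mm))
    stop("white-matter core degenerate: increase radii or reduce shell thickness")
  # one voxel of headroom covers the anti-aliasing ramp at the outer rim
  margin <- real$centre * extent_mm
  if (any(r1 + voxel_mm > pmin(margin, extent_mm - margin)))
    stop("grid too small to contain all three shells at this voxel size")

  g <- coord_grids(grid_shape)
  occ1 <- ellipsoid_occupancy(g, extent_mm, real$centre, r1, voxel_mm)
  occ2 <- ellipsoid_occupancy(g, extent_mm, real$centre, r2, voxel_mm)
  occ3 <- ellipsoid_occupancy(g, extent_mm, real$centre, r3, voxel_mm)
  # nesting can be violated by one anti-alias ramp overlapping another; clamp
  occ2 <- pmin(occ2, occ1)
  occ3 <- pmin(occ3, occ2)

  structure(list(
    pv_csf = as_volume(occ1 - occ2, voxel_mm),
    pv_gm  = as_volume(occ2 - occ3, voxel_mm),
    pv_wm  = as_volume(occ3, voxel_mm),
    tissue_means = tissue_means,
    shape_params = real,
    voxel_mm = voxel_mm,
    grid_shape = grid_shape,
    deform_seed = seed
  ), class = "tissue_phantom")
}

#' Brain mask of a phantom
#'
#' @param phantom a `tissue_phantom`.
#' @param threshold minimum total tissue partial volume.
#' @return logical array, `TRUE` inside the head.
#' @export
phantom_mask <- function(phantom, threshold = 0.5) {
  (phantom$pv_csf + phantom$pv_gm + phantom$pv_wm) >= threshold
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("tissue_phantom:", paste(x$grid_shape, collapse = "x"),
      "voxels @", x$voxel_mm, "mm\n")
  cat("  pv voxel counts (pv > 0.5): csf", sum(x$pv_csf > 0.5),
      "gm", sum(x$pv_gm > 0.5), "wm", sum(x$pv_wm > 0.5), "\n")
  invisible(x)
}
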