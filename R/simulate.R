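## Forward models: noiseless class-mixture signal x coil gain, with Rician
## noise (magnitude of a complex Gaussian) for T1/DWI and additive Gaussian
## noise for BOLD series.

## Magnitude of (signal + N(0,s), N(0,s)): the Rician observation model for
## magnitude-reconstructed MRI. s = 0 returns the signal unchanged.
rician <- function(signal, sigma) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Simulate a T1-weighted acquisition of a phantom under a coil
#'
#' The noiseless image is the partial-volume mixture of class intensities
#' multiplied by the coil gain field; Rician noise with the coil's
#' `noise_sigma` is then applied. `contrast_shift` widens (or narrows) the
#' GM/WM mean separation for this coil by a fractional amount, emulating a
#' coil-dependent change in tissue contrast.
#'
#' @param phantom a `tissue_phantom`.
#' @param coil a `coil_profile` on the same grid.
#' @param contrast_shift fractional change of the GM/WM separation (>= -1);
#'   0 leaves the nominal contrast.
#' @param seed RNG seed for the noise realization.
#' @return 3-D array with a `voxel_mm` attribute.
#' @export
simulate_t1 <- function(phantom, coil, contrast_shift = 0, seed = NULL) {
  stopifnot(inherits(phantom, "tissue_phantom"), inherits(coil, "coil_profile"))
  if (!identical(dim(coil$gain), dim(phantom$pv_gm)))
    stop("coil gain and phantom are on different grids")
  if (contrast_shift < -1) stop("contrast_shift must be >= -1")
  m <- phantom$tissue_means
  mid <- (m[["gm"]] + m[["wm"]]) / 2
  half <- (m[["wm"]] - m[["gm"]]) / 2 * (1 + contrast_shift)
  clean <- phantom$pv_csf * m[["csf"]] +
    phantom$pv_gm * (mid - half) + phantom$pv_wm * (mid + half)
  img <- with_seed(seed, rician(clean * coil$gain, coil$noise_sigma))
  as_volume(array(img, dim = dim(clean)), phantom$voxel_mm)
}

#' Diffusion gradient scheme
#'
#' Builds the default acquisition scheme: `n_b0` b=0 volumes followed by
#' `n_dir` non-collinear unit gradient directions at a single shell,
#' distributed by a spherical Fibonacci spiral.
#'
#' @param n_dir number of diffusion-weighted directions.
#' @param bval shell b-value in s/mm^2.
#' @param n_b0 number of b=0 volumes.
#' @return object of class `diffusion_scheme` with `bvals` (length
#'   `n_b0 + n_dir`) and `bvecs` (3 x n matrix of unit vectors; zero columns
#'   for b=0).
#' @export
diffusion_scheme <- function(n_dir = 60, bval = 1000, n_b0 = 1) {
  stopifnot(n_dir >= 6, n_b0 >= 1)
  if (bval < 0) stop("b-values must be non-negative")
  i <- seq_len(n_dir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i          # golden-angle spiral
  cz <- 1 - i / n_dir                    # upper hemisphere: z in (0, 1]
  sz <- sqrt(pmax(0, 1 - cz^2))
  dirs <- rbind(sz * cos(phi), sz * sin(phi), cz)
  bvecs <- cbind(matrix(0, 3, n_b0), dirs)
  dimnames(bvecs) <- NULL
  structure(list(
    bvals = c(rep(0, n_b0), rep(bval, n_dir)),
    bvecs = bvecs,
    n_b0 = as.integer(n_b0)
  ), class = "diffusion_scheme")
}

#' Write a scheme in FSL bval/bvec layout
#'
#' @param scheme a `diffusion_scheme`.
#' @param bval_path,bvec_path output text files (one row of b-values; three
#'   whitespace-separated rows for x/y/z components).
#' @return invisibly, the two paths.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(scheme$bvecs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 8), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Read an FSL bval/bvec pair
#'
#' @param bval_path,bvec_path text files in FSL layout.
#' @return a `diffusion_scheme`.
#' @export
read_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- do.call(rbind, lapply(readLines(bvec_path)[1:3],
                              function(l) scan(text = l, quiet = TRUE)))
  if (ncol(bv) != length(bvals)) stop("bval/bvec length mismatch")
  nrm <- sqrt(colSums(bv^2))
  bv[, nrm > 0] <- sweep(bv[, nrm > 0, drop = FALSE], 2, nrm[nrm > 0], "/")
  structure(list(bvals = bvals, bvecs = bv, n_b0 = sum(bvals == 0)),
            class = "diffusion_scheme")
}

## Per-class diffusion tensors (mm^2/s). WM is prolate along a smoothly
## varying in-plane direction; GM and CSF are isotropic.
tensor_class_params <- function() {
  list(wm_ev = c(1.6e-3, 0.3e-3, 0.3e-3), gm_adc = 0.8e-3, csf_adc = 3.0e-3)
}

#' Ground-truth diffusion tensor field for a phantom
#'
#' WM voxels carry a prolate tensor whose principal axis follows a smooth
#' circumferential direction field (emulating curving tracts); GM and CSF
#' are isotropic. Mixed voxels get the partial-volume weighted tensor.
#'
#' @param phantom a `tissue_phantom`.
#' @param params per-class eigenvalues, see `tensor_class_params`.
#' @return object of class `tensor_truth`: `d` (array `grid x 6`, order
#'   xx, yy, zz, xy, xz, yz), `principal_direction` (array `grid x 3`),
#'   `s0` (b0 intensity map), `mask` (head voxels).
#' @export
make_tensor_truth <- function(phantom, params = tensor_class_params()) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  gs <- phantom$grid_shape
  g <- coord_grids(gs)
  nvox <- prod(gs)

  # circumferential principal direction around the z axis
  e1 <- cbind(-(as.vector(g$y) - 0.5), as.vector(g$x) - 0.5, rep(0.25, nvox))
  nrm <- sqrt(rowSums(e1^2))
  nrm[nrm == 0] <- 1
  e1 <- e1 / nrm
  # orthonormal complement
  zref <- cbind(0, 0, 1)[rep(1, nvox), ]
  e2 <- cbind(e1[, 2] * zref[, 3] - e1[, 3] * zref[, 2],
              e1[, 3] * zref[, 1] - e1[, 1] * zref[, 3],
              e1[, 1] * zref[, 2] - e1[, 2] * zref[, 1])
  e2 <- e2 / sqrt(rowSums(e2^2))
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])

  ev <- params$wm_ev
  # D_wm = ev1 e1e1' + ev2 e2e2' + ev3 e3e3', unique elements per voxel
  outer6 <- function(v) cbind(v[, 1]^2, v[, 2]^2, v[, 3]^2,
                              v[, 1] * v[, 2], v[, 1] * v[, 3], v[, 2] * v[, 3])
  d_wm <- ev[1] * outer6(e1) + ev[2] * outer6(e2) + ev[3] * outer6(e3)
  iso6 <- function(adc) cbind(adc, adc, adc, 0, 0, 0)[rep(1, nvox), ]

  w_wm <- as.vector(phantom$pv_wm)
  w_gm <- as.vector(phantom$pv_gm)
  w_csf <- as.vector(phantom$pv_csf)
  tot <- w_wm + w_gm + w_csf
  ok <- tot > 0.01
  d <- d_wm * w_wm + iso6(params$gm_adc) * w_gm + iso6(params$csf_adc) * w_csf
  d[ok, ] <- d[ok, ] / tot[ok]
  d[!ok, ] <- 0

  s0 <- 1.0 * w_csf + 0.8 * w_gm + 0.7 * w_wm  # b0 brightness per class
  structure(list(
    d = array(d, dim = c(gs, 6L)),
    principal_direction = array(e1, dim = c(gs, 3L)),
    s0 = as_volume(array(s0, dim = gs), phantom$voxel_mm),
    mask = array(ok, dim = gs)
  ), class = "tensor_truth")
}

#' Simulate a diffusion-weighted stack
#'
#' Per volume, the signal is `S0 * exp(-b g' D g) * gain` with Rician noise.
#'
#' @param phantom a `tissue_phantom` (provides S0 via the tensor truth).
#' @param tensor_truth a `tensor_truth` on the same grid.
#' @param scheme a `diffusion_scheme`.
#' @param coil a `coil_profile` on the same grid.
#' @param noise_sigma noise level; defaults to the coil's `noise_sigma`
#'   scaled by `noise_scale`.
#' @param noise_scale multiplier on the coil noise sigma, the knob that
#'   stands in for coil-specific DWI acquisition differences.
#' @param seed RNG seed.
#' @return 4-D array (grid x volumes) with `voxel_mm` attribute.
#' @export
simulate_dwi <- function(phantom, tensor_truth, scheme, coil,
                         noise_sigma = NULL, noise_scale = 1, seed = NULL) {
  stopifnot(inherits(tensor_truth, "tensor_truth"),
            inherits(scheme, "diffusion_scheme"))
  if (any(scheme$bvals < 0)) stop("b-values must be non-negative")
  gs <- phantom$grid_shape
  if (!identical(dim(coil$gain), gs)) stop("coil grid mismatch")
  if (is.null(noise_sigma)) noise_sigma <- coil$noise_sigma * noise_scale
  nvol <- length(scheme$bvals)
  d <- matrix(tensor_truth$d, ncol = 6L)
  s0 <- as.vector(tensor_truth$s0) * as.vector(coil$gain)
  out <- array(0, dim = c(gs, nvol))
  with_seed(seed, {
    for (v in seq_len(nvol)) {
      b <- scheme$bvals[v]
      gvec <- scheme$bvecs[, v]
      q <- d[, 1] * gvec[1]^2 + d[, 2] * gvec[2]^2 + d[, 3] * gvec[3]^2 +
        2 * (d[, 4] * gvec[1] * gvec[2] + d[, 5] * gvec[1] * gvec[3] +
               d[, 6] * gvec[2] * gvec[3])
      out[, , , v] <- rician(s0 * exp(-b * q), noise_sigma)
    }
  })
  as_volume(out, phantom$voxel_mm)
}

## Band-limited unit-variance random time course: white Gaussian spectrum
## restricted to [band_hz[1], band_hz[2]], inverse-transformed and
## standardized.
bandlimited_timecourse <- function(n, tr_s, band_hz = c(0.01, 0.1)) {
  freqs <- seq(0, n - 1) / (n * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)  # two-sided
  keep <- freqs >= band_hz[1] & freqs <= band_hz[2]
  if (!any(keep)) stop("series too short for the requested band")
  spec <- complex(real = rnorm(n), imaginary = rnorm(n))
  spec[!keep] <- 0
  tc <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.vector(scale(tc))
}

#' Simulate a resting-state BOLD series
#'
#' The fluctuation signal is a sum of network spatial maps times
#' band-limited (0.01-0.1 Hz) random time courses, plus WM/CSF nuisance
#' fluctuations; the whole fluctuation field is multiplied by the coil gain
#' (receive sensitivity scales the measured signal change) and i.i.d.
#' Gaussian noise is added.
#'
#' @param phantom a `tissue_phantom` (supplies nuisance WM/CSF maps).
#' @param templates a `network_templates` object ([make_network_templates()]).
#' @param amplitudes numeric, one fluctuation amplitude per network map.
#' @param coil a `coil_profile`.
#' @param n_volumes number of time points (default 200).
#' @param tr_s repetition time in seconds (default 2.2).
#' @param nuisance_amplitude amplitude of the WM/CSF nuisance fluctuations.
#' @param noise_sigma additive noise SD; defaults to the coil's.
#' @param seed RNG seed.
#' @return 4-D array (grid x time) with `voxel_mm` attribute.
#' @export
simulate_bold <- function(phantom, templates, amplitudes, coil,
                          n_volumes = 200, tr_s = 2.2,
                          nuisance_amplitude = 0.5, noise_sigma = NULL,
                          seed = NULL) {
  stopifnot(inherits(templates, "network_templates"), n_volumes >= 20,
            tr_s > 0)
  k <- length(templates$network_maps)
  if (length(amplitudes) != k)
    stop("need one amplitude per network template (", k, ")")
  gs <- phantom$grid_shape
  for (m in c(templates$network_maps, templates$nuisance_maps))
    if (!identical(dim(m), gs)) stop("template map off the phantom grid")
  if (is.null(noise_sigma)) noise_sigma <- coil$noise_sigma
  gain <- as.vector(coil$gain)
  nvox <- prod(gs)
  with_seed(seed, {
    sig <- matrix(0, nvox, n_volumes)
    for (j in seq_len(k)) {
      if (amplitudes[j] == 0) { bandlimited_timecourse(n_volumes, tr_s); next }
      tc <- bandlimited_timecourse(n_volumes, tr_s)
      sig <- sig + amplitudes[j] * as.vector(templates$network_maps[[j]]) %o% tc
    }
    for (nm in templates$nuisance_maps) {
      tc <- bandlimited_timecourse(n_volumes, tr_s)
      sig <- sig + nuisance_amplitude * as.vector(nm) %o% tc
    }
    sig <- sig * gain
    if (noise_sigma > 0)
      sig <- sig + matrix(rnorm(nvox * n_volumes, 0, noise_sigma), nvox)
    as_volume(array(sig, dim = c(gs, n_volumes)), phantom$voxel_mm)
  })
}

#' Synthetic resting-state network template set
#'
#' Eight geometric Gaussian-blob spatial maps at canonical network
#' locations (medial/lateral visual, auditory-salience, sensorimotor,
#' default mode, executive control, left/right dorsal visual stream), plus
#' WM and CSF nuisance maps taken from the phantom's partial volumes. These
#' are synthetic stand-ins; externally supplied template maps on the same
#' grid can be used anywhere a `network_templates` object is accepted.
#'
#' @param phantom a `tissue_phantom` defining the grid and nuisance maps.
#' @param sigma_frac blob width as a fraction of the grid extent.
#' @return object of class `network_templates` with `network_maps` (list of
#'   3-D arrays), `nuisance_maps` (list: wm, csf), `names`.
#' @export
make_network_templates <- function(phantom, sigma_frac = 0.08) {
  gs <- phantom$grid_shape
  g <- coord_grids(gs)
  blob <- function(cx, cy, cz)
    exp(-((g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2) / (2 * sigma_frac^2))
  centres <- list(
    medial_visual     = list(c(0.50, 0.15, 0.45)),
    lateral_visual    = list(c(0.28, 0.20, 0.50), c(0.72, 0.20, 0.50)),
    auditory_salience = list(c(0.22, 0.50, 0.45), c(0.78, 0.50, 0.45)),
    sensorimotor      = list(c(0.50, 0.55, 0.82)),
    default_mode      = list(c(0.50, 0.80, 0.60), c(0.50, 0.28, 0.68)),
    executive_control = list(c(0.50, 0.85, 0.40)),
    dorsal_visual_l   = list(c(0.30, 0.30, 0.75)),
    dorsal_visual_r   = list(c(0.70, 0.30, 0.75))
  )
  maps <- lapply(centres, function(cs) {
    m <- Reduce(`+`, lapply(cs, function(cc) blob(cc[1], cc[2], cc[3])))
    array(m / max(m), dim = gs)
  })
  structure(list(
    network_maps = maps,
    nuisance_maps = list(wm = array(phantom$pv_wm, gs),
                         csf = array(phantom$pv_csf, gs)),
    names = names(centres)
  ), class = "network_templates")
}
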