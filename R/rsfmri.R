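## Resting-state chain: discrete-cosine high-pass filtering, volume-wise
## Gaussian smoothing, and two-stage dual regression against a set of
## network templates with WM/CSF nuisance regressors.

## Series as a (time x voxel) matrix plus the grid shape.
series_matrix <- function(series_4d) {
  d <- dim(series_4d)
  stopifnot(length(d) == 4L)
  list(mat = t(matrix(series_4d, nrow = prod(d[1:3]), ncol = d[4])),
       grid = d[1:3])
}

#' High-pass filter a BOLD series
#'
#' Removes frequency content below `cutoff_hz` by regressing out a discrete
#' cosine/sine basis spanning all periods longer than `1 / cutoff_hz` (plus
#' the series mean), voxelwise. The sine terms make the attenuation
#' phase-independent.
#'
#' @param series_4d 4-D array (grid x time).
#' @param cutoff_hz high-pass cutoff (default 0.01 Hz).
#' @param tr_s repetition time in seconds (> 0).
#' @return filtered 4-D array (zero temporal mean at every voxel).
#' @export
highpass <- function(series_4d, cutoff_hz = 0.01, tr_s) {
  if (tr_s <= 0) stop("TR must be positive")
  sm <- series_matrix(series_4d)
  n <- nrow(sm$mat)
  if (n < 2 / (cutoff_hz * tr_s) / 10)
    warning("series much shorter than the cutoff period; filter is mostly demeaning")
  k_max <- floor(2 * n * tr_s * cutoff_hz)  # DCT component k has freq k/(2 n TR)
  t_idx <- seq_len(n) - 0.5
  X <- cbind(rep(1, n), if (k_max >= 1) do.call(cbind,
    lapply(seq_len(k_max), function(k)
      cbind(cos(pi * k * t_idx / n), sin(pi * k * t_idx / n)))))
  fit <- qr(X)
  res <- sm$mat - X %*% qr.coef(fit, sm$mat)
  as_volume(array(t(res), dim = c(sm$grid, n)), voxel_size(series_4d))
}

#' Smooth a BOLD series spatially
#'
#' Volume-wise Gaussian smoothing specified as FWHM (default 6 mm, sigma
#' about 2.548 mm).
#'
#' @param series_4d 4-D array.
#' @param fwhm_mm kernel FWHM in mm (0 = identity).
#' @param voxel_mm voxel size.
#' @return smoothed 4-D array.
#' @export
smooth_fwhm <- function(series_4d, fwhm_mm = 6, voxel_mm = voxel_size(series_4d)) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(series_4d)
  sigma <- sigma_from_fwhm(fwhm_mm)
  d <- dim(series_4d)
  out <- series_4d
  for (v in seq_len(d[4]))
    out[, , , v] <- smooth_gaussian(array(series_4d[, , , v], d[1:3]),
                                    sigma, voxel_mm)
  as_volume(out, voxel_mm)
}

#' Dual regression of a BOLD series on network templates
#'
#' Stage 1 regresses each time point's image on all template and nuisance
#' spatial maps, yielding one time course per map; stage 2 regresses every
#' voxel's series on all stage-1 time courses, yielding a beta map per map.
#' z = beta / SE(beta) from the stage-2 residual variance (ordinary least
#' squares). Only network (non-nuisance) maps are returned.
#'
#' @param series_4d 4-D array (grid x time).
#' @param templates a `network_templates` object on the same grid.
#' @param mask optional logical array restricting both regressions (default:
#'   whole grid).
#' @return object of class `connectivity_maps`: `beta_maps`, `z_maps`
#'   (named lists of 3-D arrays, networks only), `timecourses` (time x map
#'   matrix, all maps including nuisance).
#' @export
dual_regression <- function(series_4d, templates, mask = NULL) {
  stopifnot(inherits(templates, "network_templates"))
  sm <- series_matrix(series_4d)
  all_maps <- c(templates$network_maps, templates$nuisance_maps)
  map_names <- c(templates$names, names(templates$nuisance_maps))
  for (m in all_maps)
    if (!identical(dim(m), sm$grid)) stop("template map off the series grid")
  n_t <- nrow(sm$mat)
  p <- length(all_maps)
  if (n_t <= p + 1) stop("series shorter than the number of regressors")

  keep <- if (is.null(mask)) seq_len(ncol(sm$mat)) else which(as.vector(mask))
  G <- vapply(all_maps, function(m) as.vector(m)[keep],
              numeric(length(keep)))
  qg <- qr(G)
  if (qg$rank < p)
    stop("spatial design rank-deficient; offending maps among: ",
         paste(map_names[qg$pivot[seq(qg$rank + 1L, p)]], collapse = ", "))
  # stage 1: time course per map
  tc <- t(qr.coef(qg, t(sm$mat[, keep, drop = FALSE])))
  colnames(tc) <- map_names

  # stage 2: per-voxel betas and OLS standard errors, on variance-normalized
  # stage-1 time courses (the FSL dual-regression convention, which makes
  # betas scale with the underlying fluctuation amplitude). Maps whose
  # stage-1 time course is identically zero (networks absent from the data)
  # are dropped from the design and get zero beta/z maps; a rank deficiency
  # among non-trivial time courses is a genuine design failure.
  tc_sd <- apply(tc, 2, stats::sd)
  silent <- tc_sd <= 1e-10 * max(tc_sd)   # numerically zero time courses
  tc_norm_mat <- sweep(tc, 2, ifelse(silent, 1, tc_sd), "/")
  tc_norm_mat[, silent] <- 0
  qt_ <- qr(tc_norm_mat)
  r2 <- qt_$rank
  if (r2 < p) {
    dropped <- qt_$pivot[seq(r2 + 1L, p)]
    if (any(!silent[dropped]))
      stop("temporal design rank-deficient; offending maps among: ",
           paste(map_names[dropped[!silent[dropped]]], collapse = ", "))
  }
  beta <- qr.coef(qt_, sm$mat)            # p x nvox, NA for dropped columns
  beta[is.na(beta)] <- 0
  resid <- sm$mat - tc_norm_mat %*% beta
  dfree <- n_t - r2
  sigma2 <- colSums(resid^2) / dfree
  r_mat <- qr.R(qt_)[seq_len(r2), seq_len(r2), drop = FALSE]
  xtx_inv_diag <- rep(Inf, p)             # dropped columns: z forced to 0
  xtx_inv_diag[qt_$pivot[seq_len(r2)]] <- diag(chol2inv(r_mat))
  se <- sqrt(outer(xtx_inv_diag, sigma2))
  z <- beta / se
  z[!is.finite(z)] <- 0                   # degenerate (noiseless) voxels

  vox <- voxel_size(series_4d)
  net_idx <- seq_along(templates$network_maps)
  to_maps <- function(m) stats::setNames(lapply(net_idx, function(j)
    as_volume(array(m[j, ], dim = sm$grid), vox)), templates$names)
  structure(list(beta_maps = to_maps(beta), z_maps = to_maps(z),
                 timecourses = tc), class = "connectivity_maps")
}

#' Standard resting-state preprocessing + dual regression for one series
#'
#' Smoothing (6 mm FWHM), high-pass filtering (0.01 Hz) and dual
#' regression, in that order.
#'
#' @param series_4d 4-D array.
#' @param templates a `network_templates`.
#' @param tr_s repetition time (s).
#' @param fwhm_mm smoothing kernel FWHM.
#' @param cutoff_hz high-pass cutoff.
#' @param mask optional analysis mask.
#' @return a `connectivity_maps` object.
#' @export
rsfmri_connectivity <- function(series_4d, templates, tr_s = 2.2,
                                fwhm_mm = 6, cutoff_hz = 0.01, mask = NULL) {
  s <- smooth_fwhm(series_4d, fwhm_mm)
  s <- highpass(s, cutoff_hz, tr_s)
  dual_regression(s, templates, mask)
}
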