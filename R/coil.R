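## Parametric coil sensitivity profiles. The two coils are characterized
## purely by their spatial gain signature and a noise amplitude:
##   8CH  - high gain anteriorly (frontal), Gaussian drop in central/medial
##          areas;
##   32CH - near-homogeneous with a posterior gain boost.
## Gains are multiplicative fields > 0 on the acquisition grid.

default_coil_params <- function(kind) {
  switch(kind,
    eight_ch = list(
      baseline = 1, anterior_ramp = 0.4, central_dip = 0.35,
      dip_sigma_frac = 0.22, noise_sigma = 0.03),
    thirty_two_ch = list(
      baseline = 1, posterior_boost = 0.25,
      boost_sigma_frac = 0.30, noise_sigma = 0.03),
    stop("unknown coil kind: ", kind)
  )
}

#' Build a parametric coil gain/noise profile
#'
#' Returns a multiplicative gain field and a complex-channel noise sigma for
#' one of two coil archetypes. The 8-channel profile has an anterior
#' (frontal) gain ramp and a central Gaussian dip; the 32-channel profile is
#' homogeneous apart from a posterior Gaussian boost, giving it a smaller
#' spatial coefficient of variation.
#'
#' @param kind `"eight_ch"` or `"thirty_two_ch"`.
#' @param grid_shape integer vector (length 2 for a single slice, 3 for a
#'   volume).
#' @param voxel_mm voxel size in mm.
#' @param params overrides of `default_coil_params(kind)`: `baseline`,
#'   `noise_sigma`, and for `eight_ch` `anterior_ramp` (a), `central_dip`
#'   (b), `dip_sigma_frac`; for `thirty_two_ch` `posterior_boost` (c),
#'   `boost_sigma_frac`.
#' @param seed unused by the deterministic default fields; reserved for
#'   jittered variants.
#' @return object of class `coil_profile` with `kind`, `gain` (array > 0),
#'   `noise_sigma`, `voxel_mm`, `params`.
#' @examples
#' cp <- make_coil_profile("eight_ch", c(32, 32, 32), voxel_mm = 6)
#' range(cp$gain)
#' @export
make_coil_profile <- function(kind = c("eight_ch", "thirty_two_ch"),
                              grid_shape = c(64, 64, 64), voxel_mm = 3,
                              params = list(), seed = NULL) {
  kind <- match.arg(kind)
  p <- utils::modifyList(default_coil_params(kind), params)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) == 2L) grid_shape <- c(grid_shape, 1L)
  g <- coord_grids(grid_shape)

  if (kind == "eight_ch") {
    dip <- exp(-((g$x - 0.5)^2 + (g$y - 0.5)^2 + (g$z - 0.5)^2) /
                 (2 * p$dip_sigma_frac^2))
    gain <- p$baseline * (1 + p$anterior_ramp * g$y - p$central_dip * dip)
  } else {
    boost <- exp(-((g$x - 0.5)^2 + (g$y - 0.15)^2 + (g$z - 0.5)^2) /
                   (2 * p$boost_sigma_frac^2))
    gain <- p$baseline * (1 + p$posterior_boost * boost)
  }
  if (any(gain <= 0))
    stop("coil parameters produce non-positive gain; reduce dip amplitude")
  if (p$noise_sigma <= 0) stop("noise_sigma must be > 0")

  structure(list(
    kind = kind,
    gain = as_volume(drop3(gain, grid_shape), voxel_mm),
    noise_sigma = p$noise_sigma,
    voxel_mm = voxel_mm,
    params = p
  ), class = "coil_profile")
}

## Keep a (nx, ny, 1) slice as 2-D for single-slice acquisitions.
drop3 <- function(arr, grid_shape) {
  if (grid_shape[3] == 1L) array(arr, dim = grid_shape[1:2]) else arr
}

#' Spatial summary of a coil gain field
#'
#' @param coil a `coil_profile`.
#' @return list with mean gain over posterior/central/anterior thirds (along
#'   the anterior-posterior axis) and the spatial coefficient of variation.
#' @export
coil_gain_summary <- function(coil) {
  d <- dim(coil$gain)
  thirds <- third_slabs(d[2])
  m <- lapply(thirds, function(idx) slab_mean(coil$gain, idx))
  list(posterior = m$posterior, central = m$central, anterior = m$anterior,
       cv = stats::sd(coil$gain) / mean(coil$gain))
}

#' @export
print.coil_profile <- function(x, ...) {
  s <- coil_gain_summary(x)
  cat("coil_profile", x$kind, ": gain",
      sprintf("[%.3f, %.3f], CV %.3f;", min(x$gain), max(x$gain), s$cv),
      "noise sigma", x$noise_sigma, "\n")
  invisible(x)
}
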