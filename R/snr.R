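## ROI-based SNR mapping from a signal image and a noise-only image, with
## the Rayleigh/Rician correction for magnitude-reconstructed noise: the SD
## of a signal-free magnitude image is sigma * sqrt((4 - pi) / 2), so the
## underlying channel sigma is SD * sqrt(2 / (4 - pi)), and
##   SNR = mean(signal ROI) / (sqrt(2 / (4 - pi)) * SD(noise ROI)).

RICIAN_SD_FACTOR <- sqrt(2 / (4 - pi))

#' Tile an image into non-overlapping square ROIs
#'
#' Blocks are tiled from the image origin; trailing partial blocks are
#' discarded.
#'
#' @param image_2d 2-D numeric matrix.
#' @param roi_size block side in voxels (default 16).
#' @return list with `blocks` (list of matrices, column-major over the block
#'   grid), `grid_dim` (rows, cols of the block grid).
#' @export
roi_partition <- function(image_2d, roi_size = 16) {
  stopifnot(is.matrix(image_2d), roi_size >= 2)
  d <- dim(image_2d)
  nb <- d %/% roi_size
  if (any(nb < 1)) stop("image smaller than one ", roi_size, "x", roi_size, " block")
  blocks <- vector("list", prod(nb))
  for (j in seq_len(nb[2])) for (i in seq_len(nb[1])) {
    ri <- ((i - 1) * roi_size + 1):(i * roi_size)
    ci <- ((j - 1) * roi_size + 1):(j * roi_size)
    blocks[[(j - 1) * nb[1] + i]] <- image_2d[ri, ci]
  }
  list(blocks = blocks, grid_dim = nb)
}

#' Rician-corrected SNR of one ROI
#'
#' @param signal_block,noise_block matrices of equal shape; the noise block
#'   comes from a signal-free magnitude (noise-only) acquisition.
#' @return `mean(signal) / (sqrt(2/(4-pi)) * sd(noise))` (sample SD), or
#'   `NA` when the noise block has zero SD (invalid ROI).
#' @export
snr_of_roi <- function(signal_block, noise_block) {
  stopifnot(identical(dim(signal_block), dim(noise_block)))
  s <- stats::sd(noise_block)
  if (!is.finite(s) || s == 0) return(NA_real_)
  mean(signal_block) / (RICIAN_SD_FACTOR * s)
}

#' ROI-wise SNR map of a signal/noise image pair
#'
#' @param signal_image,noise_image 2-D matrices of the same shape (averaged
#'   signal image and noise-only image).
#' @param roi_size ROI side in voxels (default 16).
#' @param plane acquisition plane label.
#' @return object of class `snr_map`: `values` (ROI-grid matrix of SNRs),
#'   `roi_size`, `plane`, `region_means` (mean SNR over the
#'   posterior/central/anterior thirds of the ROI grid, restricted to ROIs
#'   fully covering the imaged object), `object_roi` (logical matrix of
#'   that restriction).
#' @export
snr_map <- function(signal_image, noise_image, roi_size = 16,
                    plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  if (!identical(dim(signal_image), dim(noise_image)))
    stop("signal and noise images have different shapes")
  ps <- roi_partition(as.matrix(signal_image), roi_size)
  pn <- roi_partition(as.matrix(noise_image), roi_size)
  vals <- mapply(snr_of_roi, ps$blocks, pn$blocks)
  values <- matrix(vals, nrow = ps$grid_dim[1], ncol = ps$grid_dim[2])
  # region summaries are taken over ROIs fully covering the object: at
  # least 95% of the ROI's voxels above 30% of the image robust maximum
  thr <- 0.3 * stats::quantile(signal_image, 0.99, names = FALSE)
  cover <- vapply(ps$blocks, function(b) mean(b > thr), numeric(1))
  object_roi <- matrix(cover >= 0.95, nrow = ps$grid_dim[1])
  thirds <- third_slabs(ncol(values))
  region_means <- vapply(thirds, function(ix) {
    sel <- values[, ix][object_roi[, ix]]
    if (length(sel) == 0) NA_real_ else mean(sel, na.rm = TRUE)
  }, numeric(1))
  structure(list(values = values, roi_size = roi_size, plane = plane,
                 region_means = region_means, object_roi = object_roi),
            class = "snr_map")
}

#' Render an SNR map as a color-coded image
#'
#' Uses a fixed 0-85 color scale so maps from different coils are directly
#' comparable.
#'
#' @param x an `snr_map`.
#' @param zlim color scale limits.
#' @param ... passed to [graphics::image()].
#' @export
plot.snr_map <- function(x, zlim = c(0, 85), ...) {
  v <- pmin(pmax(x$values, zlim[1]), zlim[2])
  graphics::image(seq_len(nrow(v)), seq_len(ncol(v)), v, zlim = zlim,
                  col = grDevices::hcl.colors(64, "Spectral", rev = TRUE),
                  xlab = "ROI (left - right)",
                  ylab = "ROI (posterior - anterior)",
                  main = paste0("SNR map (", x$plane, ")"), ...)
  invisible(x)
}

#' Write an SNR map's ROI grid as CSV
#'
#' @param x an `snr_map`.
#' @param path output CSV path.
#' @export
write_snr_csv <- function(x, path) {
  utils::write.table(x$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Simulate a single-slice SNR acquisition for a coil
#'
#' Emulates the proton-density single-slice protocol: a disc-shaped uniform
#' object times the coil gain with Rician noise (averaged over `n_averages`
#' acquisitions), plus a matching noise-only image.
#'
#' @param coil a `coil_profile` built on a 2-D grid.
#' @param object_amplitude underlying signal amplitude inside the disc.
#' @param n_averages number of averaged signal acquisitions.
#' @param seed RNG seed.
#' @return list with `signal` and `noise` matrices.
#' @export
simulate_snr_slices <- function(coil, object_amplitude = 1, n_averages = 10,
                                seed = NULL) {
  stopifnot(length(dim(coil$gain)) == 2L)
  d <- dim(coil$gain)
  g <- coord_grids(c(d, 1L))
  disc <- array((g$x - 0.5)^2 + (g$y - 0.5)^2 <= 0.45^2, dim = d)
  clean <- object_amplitude * disc * coil$gain
  with_seed(seed, {
    sig <- Reduce(`+`, lapply(seq_len(n_averages), function(i)
      rician(clean, coil$noise_sigma))) / n_averages
    noise <- rician(array(0, dim = d), coil$noise_sigma)
    list(signal = matrix(sig, d[1], d[2]), noise = matrix(noise, d[1], d[2]))
  })
}
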