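## Volumes are plain R arrays (3-D scalar fields, or 4-D stacks with the
## series/volume index last) carrying a "voxel_mm" attribute: one isotropic
## in-plane/through-plane spacing in millimetres. Keeping the carrier a bare
## array means every stats/linear-algebra tool works on it directly.

#' Attach an isotropic voxel size to an array
#'
#' @param data numeric array (3-D volume or 4-D stack).
#' @param voxel_mm isotropic voxel edge length in mm.
#' @return the array with a `voxel_mm` attribute.
#' @export
as_volume <- function(data, voxel_mm = 1) {
  stopifnot(is.numeric(data), length(dim(data)) %in% c(2L, 3L, 4L), voxel_mm > 0)
  attr(data, "voxel_mm") <- as.numeric(voxel_mm)
  data
}

#' Voxel size of a volume
#'
#' @param vol array created by [as_volume()] or read by [read_volume()].
#' @param default value returned when the array carries no spacing.
#' @return voxel edge length in mm.
#' @export
voxel_size <- function(vol, default = 1) {
  v <- attr(vol, "voxel_mm")
  if (is.null(v)) default else v
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return numeric array with a `voxel_mm` attribute (first pixdim).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1]
  arr <- array(as.numeric(img), dim = dim(img))
  as_volume(arr, vox)
}

#' Write an array as a NIfTI-1 volume
#'
#' @param vol numeric array; a `voxel_mm` attribute (or `voxel_mm` arg) sets
#'   the pixdim.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_mm overrides the attribute if given.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_mm = NULL) {
  vox <- if (is.null(voxel_mm)) voxel_size(vol) else voxel_mm
  arr <- array(as.numeric(vol), dim = dim(vol))
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  # spatial spacing on the first three axes; unit spacing on time/volume
  RNifti::pixdim(img) <- c(rep(vox, min(3L, nd)), rep(1, max(0L, nd - 3L)))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

## Normalised coordinate grids in [0,1] per axis, as three arrays.
## Axis convention: x = left-right, y = posterior (0) to anterior (1),
## z = inferior-superior.
coord_grids <- function(grid_shape) {
  n <- grid_shape
  ax <- lapply(n, function(k) if (k > 1) (seq_len(k) - 0.5) / k else 0.5)
  list(
    x = array(rep(ax[[1]], times = n[2] * n[3]), dim = n),
    y = array(rep(rep(ax[[2]], each = n[1]), times = n[3]), dim = n),
    z = array(rep(ax[[3]], each = n[1] * n[2]), dim = n)
  )
}

## Index masks for thirds along the anterior-posterior (y) axis.
third_slabs <- function(n_y) {
  b1 <- floor(n_y / 3)
  b2 <- floor(2 * n_y / 3)
  list(
    posterior = seq_len(b1),
    central   = seq(b1 + 1L, b2),
    anterior  = seq(b2 + 1L, n_y)
  )
}

## Mean of a 3-D (or 2-D) volume over a slab of y indices.
slab_mean <- function(vol, y_idx) {
  d <- dim(vol)
  if (length(d) == 2L) mean(vol[, y_idx]) else mean(vol[, y_idx, ])
}
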