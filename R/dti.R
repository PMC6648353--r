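## Diffusion tensor estimation: ordinary least squares on log-signal,
##   log S = log S0 - b g' D g,
## solved once for all voxels with a shared design matrix, followed by
## closed-form symmetric 3x3 eigenvalues for FA/MD. Negative eigenvalues
## (noise) are clamped to zero before metric computation, keeping FA in
## [0, 1] and MD non-negative.

## Design matrix rows: [1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy,
## -2b gx gz, -2b gy gz] for beta = (log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensor_design <- function(scheme) {
  b <- scheme$bvals
  gx <- scheme$bvecs[1, ]; gy <- scheme$bvecs[2, ]; gz <- scheme$bvecs[3, ]
  cbind(1, -b * gx^2, -b * gy^2, -b * gz^2,
        -2 * b * gx * gy, -2 * b * gx * gz, -2 * b * gy * gz)
}

## Eigenvalues of symmetric 3x3 matrices, vectorized over rows of the
## 6-column unique-element representation (xx, yy, zz, xy, xz, yz), by the
## standard trigonometric (Cardano) method. Returns a 3-column matrix in
## descending order.
sym3_eigenvalues <- function(d6) {
  a <- d6[, 1]; b <- d6[, 2]; c <- d6[, 3]
  de <- d6[, 4]; e <- d6[, 5]; f <- d6[, 6]
  q <- (a + b + c) / 3
  p2 <- (a - q)^2 + (b - q)^2 + (c - q)^2 + 2 * (de^2 + e^2 + f^2)
  p <- sqrt(p2 / 6)
  iso <- p < .Machine$double.eps * (abs(q) + 1)
  p_safe <- ifelse(iso, 1, p)
  # det of (A - q I) / p
  a1 <- (a - q) / p_safe; b1 <- (b - q) / p_safe; c1 <- (c - q) / p_safe
  d1 <- de / p_safe; e1 <- e / p_safe; f1 <- f / p_safe
  detB <- a1 * (b1 * c1 - f1^2) - d1 * (d1 * c1 - f1 * e1) +
    e1 * (d1 * f1 - b1 * e1)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1, l2, l3)
  out[iso, ] <- cbind(q, q, q)[iso, ]
  out
}

#' Fractional anisotropy of tensor eigenvalues
#'
#' @param eigenvalues numeric length 3 (or a 3-column matrix), all >= 0.
#' @return FA in `[0, 1]`; an all-zero tensor has FA 0 by convention.
#' @export
fa_of_tensor <- function(eigenvalues) {
  ev <- rbind(eigenvalues)
  dimnames(ev) <- NULL
  num <- sqrt((ev[, 1] - ev[, 2])^2 + (ev[, 2] - ev[, 3])^2 +
                (ev[, 1] - ev[, 3])^2)
  den <- sqrt(2 * rowSums(ev^2))
  fa <- ifelse(den > 0, num / den, 0)
  if (is.vector(eigenvalues)) fa[1] else fa
}

#' Mean diffusivity of tensor eigenvalues
#'
#' @param eigenvalues numeric length 3 (or a 3-column matrix).
#' @return `(l1 + l2 + l3) / 3`.
#' @export
md_of_tensor <- function(eigenvalues) {
  ev <- rbind(eigenvalues)
  dimnames(ev) <- NULL
  md <- rowMeans(ev)
  if (is.vector(eigenvalues)) md[1] else md
}

#' Fit the diffusion tensor voxelwise
#'
#' Ordinary least squares on the log-signal with a shared design matrix;
#' voxels with any non-positive signal are excluded (`fit_ok = FALSE`).
#' Negative eigenvalues are clamped to zero before FA/MD computation and
#' flagged.
#'
#' @param dwi_stack 4-D array (grid x volumes) matching `scheme`.
#' @param scheme a `diffusion_scheme` with at least 7 volumes including one
#'   b = 0.
#' @param mask optional logical array restricting the fit.
#' @return object of class `tensor_fit`: `d` (grid x 6 array: xx, yy, zz,
#'   xy, xz, yz), `s0`, `fa`, `md`, `fit_ok`, `clamped` (voxels that needed
#'   eigenvalue clamping).
#' @export
fit_tensor <- function(dwi_stack, scheme, mask = NULL) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  nvol <- length(scheme$bvals)
  d4 <- dim(dwi_stack)
  if (length(d4) != 4L || d4[4] != nvol)
    stop("dwi stack does not match the scheme (", nvol, " volumes expected)")
  if (nvol < 7 || scheme$n_b0 < 1)
    stop("need at least 7 volumes including one b=0")
  X <- tensor_design(scheme)
  qx <- qr(X)
  if (qx$rank < 7L)
    stop("gradient scheme is rank-deficient (collinear directions)")
  gs <- d4[1:3]
  nvox <- prod(gs)
  Y <- matrix(dwi_stack, nrow = nvox, ncol = nvol)
  ok <- matrixStats_rowMin(Y) > 0
  if (!is.null(mask)) ok <- ok & as.vector(mask)
  beta <- matrix(0, nvox, 7L)
  if (any(ok))
    beta[ok, ] <- t(qr.coef(qx, t(log(Y[ok, , drop = FALSE]))))

  ev <- sym3_eigenvalues(beta[, 2:7, drop = FALSE])
  clamped <- ok & (matrixStats_rowMin(ev) < 0)
  ev[ev < 0] <- 0
  fa <- fa_of_tensor(ev)
  md <- md_of_tensor(ev)
  fa[!ok] <- 0; md[!ok] <- 0
  vox <- voxel_size(dwi_stack)
  structure(list(
    d = array(beta[, 2:7], dim = c(gs, 6L)),
    s0 = as_volume(array(exp(beta[, 1]) * ok, dim = gs), vox),
    fa = as_volume(array(fa, dim = gs), vox),
    md = as_volume(array(md, dim = gs), vox),
    fit_ok = array(ok, dim = gs),
    clamped = array(clamped, dim = gs)
  ), class = "tensor_fit")
}

matrixStats_rowMin <- function(m) do.call(pmin, as.data.frame(m))

#' White-matter analysis mask from a cohort mean FA image
#'
#' @param mean_fa 3-D array, the mean FA over all subjects and both coils.
#' @param threshold minimum FA (default 0.2).
#' @return logical array: `mean_fa >= threshold` (non-finite voxels FALSE).
#' @export
analysis_mask <- function(mean_fa, threshold = 0.2) {
  m <- is.finite(mean_fa) & mean_fa >= threshold
  array(m, dim = dim(mean_fa))
}
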