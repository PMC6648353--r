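# Shared fixtures (built once per test run) and independent oracles used to
# check the package's own implementations.

GS32 <- c(32L, 32L, 32L)
VOX32 <- 6          # 32 voxels at 6 mm = 192 mm field of view

fixture_phantom <- make_tissue_phantom(GS32, VOX32, seed = 0L)
fixture_mask <- phantom_mask(fixture_phantom)
fixture_coil8 <- make_coil_profile("eight_ch", GS32, VOX32)
fixture_coil32 <- make_coil_profile("thirty_two_ch", GS32, VOX32)

# ---- independent oracles -------------------------------------------------

# Brute-force TFCE: explicit connected-component labelling (BFS) at every
# threshold, summed directly. Independent of the package's union-find sweep.
oracle_label_components <- function(above, gs, offs) {
  # above: logical array; returns integer labels (0 outside)
  lab <- array(0L, gs)
  nxt <- 0L
  idx_all <- which(above)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      v0 <- v - 1L
      x <- v0 %% gs[1]; y <- (v0 %/% gs[1]) %% gs[2]; z <- v0 %/% (gs[1] * gs[2])
      nx <- x + offs[, 1]; ny <- y + offs[, 2]; nz <- z + offs[, 3]
      okn <- nx >= 0 & nx < gs[1] & ny >= 0 & ny < gs[2] & nz >= 0 & nz < gs[3]
      w <- 1L + nx[okn] + ny[okn] * gs[1] + nz[okn] * gs[1] * gs[2]
      w <- w[above[w] & lab[w] == 0L]
      lab[w] <- nxt
      stack <- c(stack, w)
    }
  }
  lab
}

oracle_tfce <- function(stat, mask, h = 2, e = 0.5, n_steps = 100,
                        connectivity = 26) {
  gs <- dim(stat)
  pos <- stat * (stat > 0) * mask
  hmax <- max(pos)
  out <- array(0, gs)
  if (hmax <= 0) return(out)
  dh <- hmax / n_steps
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  manh <- rowSums(abs(offs))
  offs <- offs[manh > 0 & (if (connectivity == 26) TRUE else
    if (connectivity == 18) manh <= 2 else manh == 1), , drop = FALSE]
  for (k in seq_len(n_steps)) {
    thr <- hmax * (k / n_steps)
    above <- pos >= thr & pos > 0
    if (!any(above)) next
    lab <- oracle_label_components(above, gs, offs)
    sizes <- tabulate(lab)
    idx <- which(above)
    out[idx] <- out[idx] + sizes[lab[idx]]^e * thr^h * dh
  }
  out
}

# Exhaustive sign-flip FWE p-values for the maximum-TFCE statistic,
# enumerating all 2^n sign patterns with the oracle TFCE.
oracle_signflip_p <- function(maps_a, maps_b, mask,
                              tfce_fun = function(s, m) tfce(s, m)) {
  n <- length(maps_a)
  gs <- dim(maps_a[[1]])
  D <- vapply(seq_len(n), function(i) as.numeric(maps_b[[i]] - maps_a[[i]]),
              numeric(prod(gs)))
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  null_max <- apply(signs, 1, function(s) {
    d <- D %*% s / n
    v <- (rowSums(D^2) - n * as.vector(d)^2) / (n - 1)
    tmap <- ifelse(v > 0, d / sqrt(v / n), 0)
    tf <- tfce_fun(array(tmap, gs), mask)
    c(max(tf), max(tfce_fun(array(-tmap, gs), mask)))
  })
  obs_t <- {
    d <- rowMeans(D)
    v <- (rowSums(D^2) - n * d^2) / (n - 1)
    array(ifelse(v > 0, d / sqrt(v / n), 0), gs)
  }
  tf_pos <- tfce_fun(obs_t, mask)
  tf_neg <- tfce_fun(-obs_t, mask)
  list(p_pos = array(vapply(as.numeric(tf_pos), function(x)
         mean(null_max[1, ] >= x), numeric(1)), gs),
       p_neg = array(vapply(as.numeric(tf_neg), function(x)
         mean(null_max[2, ] >= x), numeric(1)), gs))
}

# Direct (non-separable) Gaussian convolution for small arrays.
oracle_conv3 <- function(vol, kern1d) {
  r <- (length(kern1d) - 1) / 2
  gs <- dim(vol)
  out <- array(0, gs)
  for (x in 1:gs[1]) for (y in 1:gs[2]) for (z in 1:gs[3]) {
    acc <- 0
    for (i in -r:r) for (j in -r:r) for (k in -r:r) {
      xx <- x + i; yy <- y + j; zz <- z + k
      if (xx < 1 || xx > gs[1] || yy < 1 || yy > gs[2] ||
          zz < 1 || zz > gs[3]) next
      acc <- acc + vol[xx, yy, zz] * kern1d[r + 1 + i] * kern1d[r + 1 + j] *
        kern1d[r + 1 + k]
    }
    out[x, y, z] <- acc
  }
  out
}

# Hard-class phantom image: exact per-class intensities (no partial volume),
# used for clean segmentation checks.
hard_class_image <- function(phantom, means = c(csf = 0.3, gm = 0.6, wm = 0.9),
                             sigma = 0, seed = 1) {
  pv <- cbind(as.numeric(phantom$pv_csf), as.numeric(phantom$pv_gm),
              as.numeric(phantom$pv_wm))
  cls <- max.col(pv)
  img <- array(means[cls], dim = phantom$grid_shape)
  inside <- rowSums(pv) > 0.5
  img[!inside] <- 0
  if (sigma > 0) {
    set.seed(seed)
    img <- img + array(rnorm(length(img), 0, sigma), dim = dim(img))
  }
  list(image = as_volume(img, phantom$voxel_mm),
       classes = array(cls * inside, dim = phantom$grid_shape))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
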