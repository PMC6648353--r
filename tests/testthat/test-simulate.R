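noiseless_coil <- function(kind = "eight_ch")
  make_coil_profile(kind, GS32, VOX32, params = list(noise_sigma = 1e-12))

test_that("noiseless T1 equals the gain-weighted tissue mixture", {
  cp <- noiseless_coil()
  img <- simulate_t1(fixture_phantom, cp, contrast_shift = 0, seed = 1)
  m <- fixture_phantom$tissue_means
  expected <- (fixture_phantom$pv_csf * m[["csf"]] +
               fixture_phantom$pv_gm * m[["gm"]] +
               fixture_phantom$pv_wm * m[["wm"]]) * cp$gain
  expect_equal(as.numeric(img), as.numeric(expected), tolerance = 1e-6)
})

test_that("contrast_shift widens the GM/WM separation symmetrically", {
  # uniform gain so regional gain differences cannot mask the midpoint
  cp <- make_coil_profile("eight_ch", GS32, VOX32,
                          params = list(anterior_ramp = 0, central_dip = 0,
                                        noise_sigma = 1e-12))
  img0 <- simulate_t1(fixture_phantom, cp, 0, seed = 1)
  img1 <- simulate_t1(fixture_phantom, cp, 0.1, seed = 1)
  wm <- fixture_phantom$pv_wm > 0.99
  gm <- fixture_phantom$pv_gm > 0.99
  expect_gt(mean(img1[wm]), mean(img0[wm]))  # WM brighter
  expect_lt(mean(img1[gm]), mean(img0[gm]))  # GM darker
  # midpoint intensity unchanged
  expect_equal(mean(img1[wm]) + mean(img1[gm]),
               mean(img0[wm]) + mean(img0[gm]), tolerance = 1e-6)
})

test_that("magnitude noise follows Rayleigh statistics in background", {
  cp <- make_coil_profile("eight_ch", GS32, VOX32,
                          params = list(noise_sigma = 0.05))
  img <- simulate_t1(fixture_phantom, cp, seed = 3)
  bg <- (fixture_phantom$pv_csf + fixture_phantom$pv_gm +
           fixture_phantom$pv_wm) == 0
  expect_gt(sum(bg), 1e4)
  sigma <- cp$noise_sigma
  # Rayleigh mean sigma*sqrt(pi/2) and SD sigma*sqrt((4-pi)/2)
  expect_equal(mean(img[bg]), sigma * sqrt(pi / 2), tolerance = 0.02)
  ratio <- stats::sd(img[bg]) / sigma
  expect_gt(ratio, 0.95 * sqrt((4 - pi) / 2))
  expect_lt(ratio, 1.05 * sqrt((4 - pi) / 2))
  # determinism
  expect_identical(img, simulate_t1(fixture_phantom, cp, seed = 3))
})

test_that("diffusion scheme has unit, non-collinear directions", {
  sc <- diffusion_scheme()
  expect_length(sc$bvals, 61)
  expect_equal(sum(sc$bvals == 0), 1)
  nrm <- colSums(sc$bvecs^2)
  expect_equal(nrm[sc$bvals > 0], rep(1, 60), tolerance = 1e-12,
               ignore_attr = TRUE)
  # no pair of directions collinear
  G <- t(sc$bvecs[, sc$bvals > 0])
  dots <- abs(G %*% t(G)); diag(dots) <- 0
  expect_lt(max(dots), 0.999)
  expect_error(diffusion_scheme(bval = -5), "non-negative")
})

test_that("bval/bvec files round-trip in FSL layout", {
  sc <- diffusion_scheme(n_dir = 12)
  bv <- tempfile(); bvec <- tempfile()
  write_scheme(sc, bv, bvec)
  sc2 <- read_scheme(bv, bvec)
  expect_equal(sc2$bvals, sc$bvals)
  expect_equal(sc2$bvecs, sc$bvecs, tolerance = 1e-7)
  expect_length(readLines(bvec), 3)
})

test_that("noiseless DWI signal follows the tensor attenuation model", {
  cp <- noiseless_coil()
  truth <- make_tensor_truth(fixture_phantom)
  sc <- diffusion_scheme(n_dir = 12)
  dwi <- simulate_dwi(fixture_phantom, truth, sc, cp, noise_sigma = 0, seed = 1)
  # b=0 volume is S0 x gain exactly
  expect_equal(as.numeric(dwi[, , , 1]),
               as.numeric(truth$s0 * cp$gain), tolerance = 1e-12)
  # the per-voxel attenuation matches exp(-b g' D g) exactly
  set.seed(2)
  vox <- sample(which(fixture_phantom$pv_wm > 0.5), 5)
  for (v in vox) {
    ijk <- arrayInd(v, GS32)
    d <- truth$d[ijk[1], ijk[2], ijk[3], ]
    s0v <- dwi[ijk[1], ijk[2], ijk[3], 1]
    for (k in 2:13) {
      g <- sc$bvecs[, k]
      q <- d[1] * g[1]^2 + d[2] * g[2]^2 + d[3] * g[3]^2 +
        2 * (d[4] * g[1] * g[2] + d[5] * g[1] * g[3] + d[6] * g[2] * g[3])
      expect_equal(dwi[ijk[1], ijk[2], ijk[3], k], s0v * exp(-1000 * q),
                   tolerance = 1e-12)
    }
  }
  # a perfectly isotropic truth attenuates by exp(-b*adc) in every direction
  iso <- truth
  iso$d <- array(rep(c(1e-3, 1e-3, 1e-3, 0, 0, 0),
                     each = prod(GS32)), dim = c(GS32, 6L))
  dwi_iso <- simulate_dwi(fixture_phantom, iso, sc, cp, noise_sigma = 0,
                          seed = 1)
  v1 <- which(fixture_phantom$pv_wm > 0.9)[1]
  ijk <- arrayInd(v1, GS32)
  att <- dwi_iso[ijk[1], ijk[2], ijk[3], -1] / dwi_iso[ijk[1], ijk[2], ijk[3], 1]
  expect_equal(att, rep(exp(-1), 12), tolerance = 1e-12)
})

test_that("attenuation is strongest along the principal direction", {
  # stick-like tensor along x
  ph <- fixture_phantom
  gvec_para <- c(1, 0, 0); gvec_perp <- c(0, 0, 1)
  d6 <- c(1.6e-3, 0.1e-3, 0.1e-3, 0, 0, 0)
  q <- function(g) d6[1] * g[1]^2 + d6[2] * g[2]^2 + d6[3] * g[3]^2
  expect_lt(exp(-1000 * q(gvec_para)), exp(-1000 * q(gvec_perp)))
  # and in the simulated field: WM voxels attenuate more along e1
  truth <- make_tensor_truth(ph)
  wmv <- which(ph$pv_wm > 0.99)[1]
  idx <- arrayInd(wmv, dim(ph$pv_wm))
  e1 <- truth$principal_direction[idx[1], idx[2], idx[3], ]
  d <- truth$d[idx[1], idx[2], idx[3], ]
  qf <- function(g) d[1] * g[1]^2 + d[2] * g[2]^2 + d[3] * g[3]^2 +
    2 * (d[4] * g[1] * g[2] + d[5] * g[1] * g[3] + d[6] * g[2] * g[3])
  perp <- c(-e1[2], e1[1], 0); perp <- perp / sqrt(sum(perp^2))
  expect_gt(qf(e1), qf(perp))
})

test_that("BOLD forward model is linear in templates and amplitudes", {
  cp <- noiseless_coil()
  tmpl <- make_network_templates(fixture_phantom)
  zero <- simulate_bold(fixture_phantom, tmpl, rep(0, 8), cp,
                        n_volumes = 24, nuisance_amplitude = 0,
                        noise_sigma = 0, seed = 1)
  expect_equal(max(abs(zero)), 0)
  one <- simulate_bold(fixture_phantom, tmpl, c(1, rep(0, 7)), cp,
                       n_volumes = 24, nuisance_amplitude = 0,
                       noise_sigma = 0, seed = 1)
  # every voxel's series proportional to the single active time course
  sm <- matrix(one, ncol = 24)
  ref <- sm[which.max(abs(sm[, 1])), ]
  proj <- sm %*% ref / sum(ref^2)
  expect_equal(sm, proj %*% t(ref), tolerance = 1e-8)
  expect_identical(one, simulate_bold(fixture_phantom, tmpl, c(1, rep(0, 7)),
                                      cp, n_volumes = 24,
                                      nuisance_amplitude = 0,
                                      noise_sigma = 0, seed = 1))
  expect_error(simulate_bold(fixture_phantom, tmpl, rep(0, 3), cp),
               "one amplitude per network")
})
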