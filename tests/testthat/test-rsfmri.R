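make_series <- function(tc_list, maps, gs = c(8, 8, 8)) {
  n <- length(tc_list[[1]])
  s <- matrix(0, prod(gs), n)
  for (j in seq_along(tc_list))
    s <- s + as.numeric(maps[[j]]) %o% tc_list[[j]]
  as_volume(array(s, c(gs, n)), 3)
}

sinusoid_series <- function(freq_hz, n = 200, tr = 2.2, gs = c(4, 4, 4)) {
  tc <- sin(2 * pi * freq_hz * (seq_len(n) - 1) * tr)
  as_volume(array(rep(tc, each = prod(gs)), c(gs, n)), 3)
}

test_that("high-pass filter removes slow drift and keeps the passband", {
  const <- as_volume(array(5, c(4, 4, 4, 40)), 3)
  expect_equal(max(abs(highpass(const, 0.01, 2.2))), 0)

  keep <- highpass(sinusoid_series(0.05), 0.01, 2.2)
  amp_in <- max(abs(sinusoid_series(0.05)[1, 1, 1, ]))
  expect_gt(max(abs(keep[1, 1, 1, ])) / amp_in, 0.95)

  drop <- highpass(sinusoid_series(0.002), 0.01, 2.2)
  amp_drift <- max(abs(sinusoid_series(0.002)[1, 1, 1, ]))
  expect_lt(max(abs(drop[1, 1, 1, ])) / amp_drift, 0.10)

  expect_error(highpass(const, 0.01, tr_s = 0), "positive")
})

test_that("FWHM smoothing matches the sigma conversion and is optional", {
  s <- as_volume(array(rnorm(4^3 * 5), c(4, 4, 4, 5)), 3)
  expect_identical(smooth_fwhm(s, 0), s)
  expect_equal(sigma_from_fwhm(6), 2.548, tolerance = 1e-3)
  # spatial autocorrelation increases after smoothing
  sm <- smooth_fwhm(s, fwhm_mm = 6, voxel_mm = 3)
  lag_cor <- function(x) {
    v <- x[, , , 1]
    stats::cor(as.numeric(v[-4, , ]), as.numeric(v[-1, , ]))
  }
  expect_gt(lag_cor(sm), lag_cor(s))
})

synthetic_templates <- function(gs = c(8, 8, 8)) {
  g <- coilbias:::coord_grids(gs)
  blob <- function(cx, cy, cz)
    array(exp(-((g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2) / 0.02), gs)
  structure(list(
    network_maps = list(net1 = blob(0.3, 0.3, 0.5), net2 = blob(0.7, 0.7, 0.5)),
    nuisance_maps = list(wm = blob(0.5, 0.5, 0.2), csf = blob(0.5, 0.5, 0.8)),
    names = c("net1", "net2")
  ), class = "network_templates")
}

test_that("dual regression recovers time course and map from clean data", {
  tm <- synthetic_templates()
  set.seed(3)
  tc1 <- rnorm(50)
  noise_tc <- list(rnorm(50), rnorm(50), rnorm(50))
  series <- make_series(c(list(tc1), noise_tc[1]),
                        list(tm$network_maps$net1, tm$nuisance_maps$wm))
  dr <- dual_regression(series, tm)
  cs <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(abs(cs(dr$timecourses[, "net1"], tc1)), 0.999)
  expect_gt(abs(cs(as.numeric(dr$beta_maps$net1),
                   as.numeric(tm$network_maps$net1))), 0.999)
  # the silent network's betas vanish
  expect_lt(max(abs(dr$beta_maps$net2)), 1e-8 * max(abs(dr$beta_maps$net1)))
})

test_that("stage-2 betas are linear in the injected amplitude", {
  tmpl <- make_network_templates(fixture_phantom)
  cp <- make_coil_profile("eight_ch", GS32, VOX32,
                          params = list(anterior_ramp = 0, central_dip = 0,
                                        noise_sigma = 1e-12))
  mk <- function(a) simulate_bold(fixture_phantom, tmpl,
                                  c(a, rep(0.7, 7)), cp,
                                  n_volumes = 40, nuisance_amplitude = 0.3,
                                  noise_sigma = 0, seed = 9)
  b1 <- dual_regression(mk(1), tmpl)
  b2 <- dual_regression(mk(2), tmpl)
  core <- tmpl$network_maps$medial_visual > 0.5
  r <- mean(b2$beta_maps$medial_visual[core]) /
    mean(b1$beta_maps$medial_visual[core])
  expect_equal(r, 2, tolerance = 0.02)
})

test_that("nuisance-only data yields null network z-maps", {
  tm <- synthetic_templates()
  set.seed(8)
  series <- make_series(list(rnorm(80), rnorm(80)),
                        list(tm$nuisance_maps$wm, tm$nuisance_maps$csf))
  noisy <- series + array(rnorm(length(series), 0, 0.05), dim(series))
  dr <- dual_regression(as_volume(noisy, 3), tm)
  # silent-network z-maps are calibrated null statistics: centered on zero
  # with approximately unit spread
  for (zm in dr$z_maps) {
    expect_lt(abs(mean(zm)), 0.2)
    expect_gt(stats::sd(zm), 0.8)
    expect_lt(stats::sd(zm), 1.2)
    expect_lt(mean(abs(zm) > 2), 0.10)
  }
})

test_that("z and beta maps are invariant to template rescaling", {
  tm <- synthetic_templates()
  set.seed(4)
  series <- make_series(list(rnorm(60), rnorm(60)),
                        list(tm$network_maps$net1, tm$network_maps$net2))
  series <- as_volume(series + array(rnorm(length(series), 0, 0.1),
                                     dim(series)), 3)
  tm_scaled <- tm
  tm_scaled$network_maps$net1 <- 5 * tm$network_maps$net1
  d1 <- dual_regression(series, tm)
  d2 <- dual_regression(series, tm_scaled)
  expect_equal(d2$z_maps$net1, d1$z_maps$net1, tolerance = 1e-8)
  # betas are expressed per unit-variance time course, so the template's
  # scale cancels between the two regression stages
  expect_equal(as.numeric(d2$beta_maps$net1),
               as.numeric(d1$beta_maps$net1), tolerance = 1e-8)
})

test_that("rank-deficient template sets are rejected by name", {
  tm <- synthetic_templates()
  tm$network_maps$net2 <- tm$network_maps$net1  # duplicate map
  set.seed(5)
  series <- as_volume(array(rnorm(8^3 * 30), c(8, 8, 8, 30)), 3)
  expect_error(dual_regression(series, tm), "rank-deficient")
  expect_error(dual_regression(as_volume(array(1, c(8, 8, 8, 4)), 3),
                               synthetic_templates()), "shorter")
})
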