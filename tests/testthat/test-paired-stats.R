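rand_maps <- function(n, gs = c(6, 6, 6), seed = 1, f = rnorm) {
  set.seed(seed)
  lapply(seq_len(n), function(i) array(f(prod(gs)), gs))
}

test_that("paired t-map matches hand arithmetic and pairing invariance", {
  gs <- c(4, 4, 4)
  mask <- array(TRUE, gs)
  a <- rand_maps(3, gs, seed = 1)
  expect_equal(max(abs(paired_t(a, a, mask))), 0)

  # d = {1, 2, 3} at every voxel: t = 2 / (1 / sqrt(3)) = 3.4641
  b <- Map(function(m, k) m + k, a, 1:3)
  tmap <- paired_t(a, b, mask)
  expect_equal(as.numeric(tmap), rep(2 * sqrt(3), 64), tolerance = 1e-10)

  # reordering subjects consistently leaves t unchanged
  perm <- c(3, 1, 2)
  expect_equal(paired_t(a[perm], b[perm], mask), tmap, tolerance = 1e-12)

  # zero-variance voxels flagged with t = 0
  b2 <- lapply(a, function(m) m + 1)
  t2 <- paired_t(a, b2, mask)
  expect_equal(max(abs(t2)), 0)
  expect_true(all(attr(t2, "zero_variance")))
})

test_that("TFCE matches the brute-force threshold-sum oracle", {
  gs <- c(10, 10, 10)
  mask <- array(TRUE, gs)
  # single-voxel map: closed-form sum over 100 thresholds
  v <- array(0, gs); v[5, 5, 5] <- 1
  tf <- tfce(v, mask)
  expect_equal(tf[5, 5, 5], sum((1:100 / 100)^2 * 0.01), tolerance = 1e-12)
  expect_equal(sum(tf > 0), 1)
  # all-zero map
  expect_equal(max(tfce(array(0, gs), mask)), 0)
  # random smooth map vs oracle, both connectivities
  set.seed(21)
  stat <- smooth_gaussian(as_volume(array(rnorm(1000), gs), 1), 1.2, 1)
  stat <- stat / max(abs(stat))
  for (conn in c(6, 26)) {
    got <- tfce(stat, mask, connectivity = conn)
    want <- oracle_tfce(stat, mask, connectivity = conn)
    expect_lt(max(abs(got - want)) / max(want), 1e-6)
  }
  expect_error(tfce(v, array(FALSE, gs)), "empty")
})

test_that("TFCE is c^(H+1)-homogeneous with adaptive step size", {
  gs <- c(8, 8, 8)
  mask <- array(TRUE, gs)
  set.seed(31)
  stat <- array(rnorm(prod(gs)), gs)
  t1 <- tfce(stat, mask)
  for (cc in c(0.5, 3, 40)) {
    tc <- tfce(cc * stat, mask)
    expect_equal(tc, cc^3 * t1, tolerance = 1e-10)
  }
})

test_that("sampled sign-flip p-values equal exhaustive enumeration", {
  gs <- c(6, 6, 6)
  mask <- array(TRUE, gs)
  a <- rand_maps(5, gs, seed = 41)
  b <- rand_maps(5, gs, seed = 42, f = function(n) rnorm(n, mean = 0.3))
  r1 <- permutation_fwe(a, b, mask, n_perm = 1000, seed = 7)
  r2 <- permutation_fwe(a, b, mask, n_perm = 1000, seed = 12345)
  expect_true(r1$exhaustive)
  expect_equal(r1$n_permutations, 32)
  expect_identical(r1$p_fwe_pos, r2$p_fwe_pos)
  expect_identical(r1$p_fwe_neg, r2$p_fwe_neg)
  # independent enumeration oracle; sign patterns whose TFCE maximum ties
  # the observed value to within rounding can fall on either side of the
  # >= comparison, so agreement is to one tie step of the discrete p scale
  or <- oracle_signflip_p(a, b, mask)
  expect_lte(max(abs(r1$p_fwe_pos - or$p_pos)), 1 / 32)
  expect_lte(max(abs(r1$p_fwe_neg - or$p_neg)), 1 / 32)
  expect_gte(mean(r1$p_fwe_pos == or$p_pos), 0.99)
  # p >= 1/n_permutations everywhere
  expect_gte(min(r1$p_fwe_pos), 1 / 32)
})

test_that("p-values are monotone in TFCE and symmetric under negation", {
  gs <- c(6, 6, 6)
  mask <- array(TRUE, gs)
  a <- rand_maps(8, gs, seed = 51)
  b <- rand_maps(8, gs, seed = 52, f = function(n) rnorm(n, 0.2))
  r <- permutation_fwe(a, b, mask, n_perm = 300, seed = 3)
  ord <- order(r$tfce_pos[mask])
  p_ord <- r$p_fwe_pos[mask][ord]
  expect_true(all(diff(p_ord) <= 1e-12))
  # swapping conditions swaps the two directions exactly
  rs <- permutation_fwe(b, a, mask, n_perm = 300, seed = 3)
  expect_equal(rs$tfce_pos, r$tfce_neg, tolerance = 1e-12)
  expect_equal(rs$p_fwe_neg, r$p_fwe_pos, tolerance = 1e-12)
  # determinism
  r2 <- permutation_fwe(a, b, mask, n_perm = 300, seed = 3)
  expect_identical(r2$p_fwe_pos, r$p_fwe_pos)
  # sampling mode (2^8 > 100 permutations) requires an explicit seed
  expect_error(permutation_fwe(a, b, mask, n_perm = 100), "seed")
})

test_that("effect summaries follow their definitions", {
  gs <- c(5, 5, 5)
  a <- rand_maps(6, gs, seed = 61, f = function(n) runif(n, 1, 2))
  b <- lapply(a, function(m) 1.062 * m)
  mask <- array(TRUE, gs)
  s <- summarize_effect(a, b, mask)
  expect_equal(s$pct_change, 6.2, tolerance = 1e-9)

  # constant per-subject difference: degenerate, infinite d
  b2 <- lapply(a, function(m) m + 0.5)
  s2 <- summarize_effect(a, b2, mask)
  expect_true(s2$degenerate)
  expect_identical(s2$effect_size, Inf)

  # swapping a and b negates the effect size exactly
  b3 <- Map(function(m, k) m + k * 0.1, a, seq_len(6))
  s3 <- summarize_effect(a, b3, mask)
  s3r <- summarize_effect(b3, a, mask)
  expect_equal(s3r$effect_size, -s3$effect_size, tolerance = 1e-12)
  expect_lt(s3r$pct_change, 0)

  expect_equal(summarize_effect(a, b, array(FALSE, gs))$n_voxels, 0)
})

test_that("injected regional effects are recovered with matching sign", {
  gs <- GS32
  mask <- fixture_mask
  region <- array(FALSE, gs); region[10:16, 10:16, 10:16] <- TRUE
  region <- region & mask
  set.seed(71)
  base <- function() smooth_gaussian(
    as_volume(array(1 + 0.3 * rnorm(prod(gs)), gs), VOX32), 6, VOX32)
  a <- replicate(20, base(), simplify = FALSE)
  b <- lapply(a, function(m) {
    m2 <- m + array(rnorm(prod(gs), 0, 0.02), gs)
    m2[region] <- m2[region] * 1.05
    m2
  })
  r <- permutation_fwe(a, b, mask, n_perm = 400, seed = 5)
  expect_gt(sum(r$sig_mask_pos), 0)
  expect_gte(dice(r$sig_mask_pos, region), 0.5)
  expect_gt(r$effect_size_pos, 0)
})
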