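fake_cohort_meta <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = runif(n, 45, 80), sex = sample(c("F", "M"), n, TRUE))
}

test_that("matched split hits the requested sizes with balanced ages", {
  meta <- fake_cohort_meta(77)
  sp <- split_cohort(meta, 39)
  expect_length(sp$template, 39)
  expect_length(sp$validation, 38)
  expect_length(intersect(sp$template, sp$validation), 0)
  # alternate assignment keeps age means close, over many random cohorts
  for (s in 1:10) {
    m <- fake_cohort_meta(40 + s, seed = s)
    spl <- split_cohort(m, 20)
    diff_age <- abs(mean(m$age[spl$template]) - mean(m$age[spl$validation]))
    expect_lte(diff_age, 0.5 * stats::sd(m$age))
  }
  # degenerate covariates still split to the requested sizes
  same <- data.frame(age = rep(60, 77), sex = rep("F", 77))
  sp2 <- split_cohort(same, 39)
  expect_length(sp2$template, 39)
  expect_error(split_cohort(meta, 77), "n_template")
  expect_warning(split_cohort(data.frame(age = c(50, 60, 70),
                                         sex = c("F", "M", "M")), 1),
                 "single subject")
})

test_that("scaling estimation reduces to the exact ratio without noise", {
  gs <- c(32, 32, 32)
  g <- coilbias:::coord_grids(gs)
  base <- array(0.5 + 0.4 * exp(-((g$x - 0.5)^2 + (g$y - 0.5)^2) / 0.1), gs)
  imgs8 <- list(as_volume(base, 4), as_volume(base * 1.0, 4))
  # identical images: ratio identically 1
  f1 <- estimate_scaling(imgs8, imgs8, voxel_mm = 4, filter_mm = 0)
  expect_equal(range(f1$ratio), c(1, 1))
  # known smooth gain: exact recovery on the valid mask
  gain <- array(1 + 0.3 * g$y, gs)
  imgs32 <- lapply(imgs8, function(m) as_volume(m * gain, 4))
  f2 <- estimate_scaling(imgs8, imgs32, voxel_mm = 4, filter_mm = 0)
  expect_lt(max(abs((f2$ratio - gain)[f2$valid_mask])), 1e-6)
  expect_true(all(f2$ratio[!f2$valid_mask] == 1))
  expect_error(estimate_scaling(imgs8[1], imgs32[1]), ">= 2")
})

test_that("ratio error shrinks with template size under noise", {
  cfg <- cohort_config(modalities = "t1")
  coh <- make_cohort(24, cfg, seed = 13)
  imgs <- cohort_images(coh, "t1")
  truth <- coh$coils$b$gain / coh$coils$a$gain
  rmse <- vapply(c(4, 12, 24), function(n) {
    f <- estimate_scaling(imgs$a[1:n], imgs$b[1:n], voxel_mm = VOX32)
    sqrt(mean((f$ratio - truth)[f$valid_mask]^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("applying a field is exact, reversible and modality-guarded", {
  gs <- c(32, 32, 32)
  set.seed(3)
  img <- as_volume(array(abs(rnorm(prod(gs), 1, 0.2)), gs), 4)
  base <- list(img, as_volume(img * 1.01, 4))
  f1 <- estimate_scaling(base, base, voxel_mm = 4)
  scaled <- apply_scaling(img, f1)
  expect_equal(as.numeric(scaled),
               as.numeric(img * f1$ratio), tolerance = 1e-12)
  # apply then divide restores the original
  back <- scaled / f1$ratio
  expect_lt(max(abs(back - img)[f1$valid_mask]), 1e-10)
  # identity field
  fid <- f1; fid$ratio[] <- 1
  expect_equal(as.numeric(apply_scaling(img, fid)), as.numeric(img))
  expect_error(apply_scaling(img, f1, modality = "dwi"), "modality mismatch")
  expect_error(apply_scaling(array(1, c(8, 8, 8)), f1), "different grids")
})

test_that("harmonization removes a purely multiplicative coil difference", {
  cfg <- cohort_config(modalities = "t1")
  coh <- make_cohort(32, cfg, seed = 17)
  imgs <- cohort_images(coh, "t1")
  sp <- split_cohort(coh, 16)
  field <- estimate_scaling(imgs$a[sp$template], imgs$b[sp$template],
                            voxel_mm = VOX32)
  # mean-intensity gap across validation subjects shrinks by >= 80%
  vmean <- function(lst) Reduce(`+`, lapply(lst, as.numeric)) / length(lst)
  m8 <- vmean(imgs$a[sp$validation])
  m32 <- vmean(imgs$b[sp$validation])
  m8s <- vmean(lapply(imgs$a[sp$validation], apply_scaling, field = field))
  gap_pre <- mean(abs(m32 - m8)[field$valid_mask])
  gap_post <- mean(abs(m32 - m8s)[field$valid_mask])
  expect_gte(1 - gap_post / gap_pre, 0.8)

  rep <- validate_harmonization(imgs$a[sp$validation], imgs$b[sp$validation],
                                field, fixture_mask,
                                template_ids = sp$template,
                                validation_ids = sp$validation,
                                n_perm = 300, seed = 2)
  pre_sig <- sum(rep$pre$sig_mask_pos) + sum(rep$pre$sig_mask_neg)
  post_sig <- sum(rep$post$sig_mask_pos) + sum(rep$post$sig_mask_neg)
  expect_gt(pre_sig, 0)        # the raw coil gain difference is detected
  expect_lt(post_sig, pre_sig) # and substantially removed by scaling
  expect_lt(post_sig, 0.01 * sum(fixture_mask))
})

test_that("validation guards against template leakage and trivial fields", {
  gs <- c(32, 32, 32)
  set.seed(5)
  a <- lapply(1:5, function(i) as_volume(array(abs(rnorm(prod(gs), 1, .1)), gs), 4))
  b <- lapply(a, function(m) as_volume(m + array(rnorm(prod(gs), 0, .1), gs), 4))
  fid <- estimate_scaling(a, a, voxel_mm = 4)  # ratio = 1
  mask <- array(TRUE, gs)
  expect_error(validate_harmonization(a, b, fid, mask,
                                      template_ids = 1:4,
                                      validation_ids = 4:8), "overlap")
  rep <- validate_harmonization(a, b, fid, mask, n_perm = 200, seed = 4)
  expect_identical(rep$pre$p_fwe_pos, rep$post$p_fwe_pos)
  expect_identical(rep$pre$t_map, rep$post$t_map)
})

test_that("scaling fields round-trip through NIfTI + YAML", {
  gs <- c(32, 32, 32)
  set.seed(6)
  a <- lapply(1:3, function(i) as_volume(array(abs(rnorm(prod(gs), 1, .1)), gs), 4))
  b <- lapply(a, function(m) as_volume(m * 1.1, 4))
  f <- estimate_scaling(a, b, voxel_mm = 4, modality = "t1")
  prefix <- file.path(tempdir(), "field_test")
  write_scaling_field(f, prefix)
  f2 <- read_scaling_field(prefix)
  expect_equal(as.numeric(f2$ratio), as.numeric(f$ratio), tolerance = 1e-6)
  expect_identical(f2$modality, "t1")
  expect_equal(f2$n_template, 3)
  expect_equal(sum(f2$valid_mask), sum(f$valid_mask))
})
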