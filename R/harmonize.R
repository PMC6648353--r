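## Voxel-specific scaling-factor harmonization: split the cohort into
## age/sex-matched template and validation halves, estimate the voxelwise
## ratio of coil-averaged images (32CH mean / 8CH mean) on the template
## half, median-filter it, multiply the validation 8CH images by it, and
## verify by re-running the paired inference before and after.

#' Age/sex-matched cohort split
#'
#' Within each sex stratum, subjects are sorted by age and assigned
#' alternately to the template and validation groups, then rebalanced to
#' hit `n_template` exactly by moving the subjects whose age is closest to
#' the receiving group's mean. Deterministic given the cohort; `seed` only
#' breaks age ties.
#'
#' @param cohort a `coil_cohort`, or a data frame with `age` and `sex`.
#' @param n_template target template-group size (< cohort size).
#' @param seed tie-break seed.
#' @return list of class `cohort_split`: `template`, `validation` (integer
#'   subject indices), `report` (data frame of group sizes and covariate
#'   means).
#' @export
split_cohort <- function(cohort, n_template, seed = 1L) {
  if (inherits(cohort, "coil_cohort")) {
    age <- vapply(cohort$subjects, `[[`, numeric(1), "age")
    sex <- vapply(cohort$subjects, `[[`, character(1), "sex")
  } else {
    age <- cohort$age; sex <- cohort$sex
  }
  n <- length(age)
  if (n_template >= n || n_template < 1) stop("n_template must be in [1, n)")

  tmpl <- logical(n)
  flip <- TRUE   # alternation phase carried across strata to balance counts
  for (s in unique(sort(sex))) {
    idx <- which(sex == s)
    if (length(idx) == 1) {
      warning("sex stratum '", s, "' has a single subject; assigned to the ",
              "larger group")
      tmpl[idx] <- n_template > n - n_template
      next
    }
    ord <- idx[order(age[idx], with_seed(seed, runif(length(idx))))]
    for (i in seq_along(ord)) { tmpl[ord[i]] <- flip; flip <- !flip }
  }
  # rebalance to exactly n_template, moving age-central subjects
  move_one <- function(from_tmpl) {
    pool <- which(tmpl == from_tmpl)
    target_mean <- mean(age[tmpl != from_tmpl])
    mv <- pool[which.min(abs(age[pool] - target_mean))]
    tmpl[mv] <<- !from_tmpl
  }
  while (sum(tmpl) > n_template) move_one(TRUE)
  while (sum(tmpl) < n_template) move_one(FALSE)

  report <- data.frame(
    group = c("template", "validation"),
    n = c(sum(tmpl), n - sum(tmpl)),
    mean_age = c(mean(age[tmpl]), mean(age[!tmpl])),
    sd_age = c(stats::sd(age[tmpl]), stats::sd(age[!tmpl])),
    frac_female = c(mean(sex[tmpl] == "F"), mean(sex[!tmpl] == "F"))
  )
  structure(list(template = which(tmpl), validation = which(!tmpl),
                 report = report), class = "cohort_split")
}

#' Estimate a voxel-specific scaling field from template subjects
#'
#' The ratio image is `mean(32CH images) / mean(8CH images)` voxelwise,
#' median-filtered with a cubic window of about `filter_mm` a side, on the
#' valid mask where the 8CH mean exceeds `floor_frac` of its robust (99th
#' percentile) maximum; outside the valid mask the ratio is 1.
#'
#' @param imgs_8ch,imgs_32ch lists of 3-D arrays from the template
#'   subjects (>= 2 each).
#' @param voxel_mm voxel size in mm.
#' @param filter_mm median-filter kernel size (default 5 mm); 0 disables.
#' @param floor_frac denominator floor as a fraction of the robust maximum.
#' @param modality label recorded on the field and checked at application.
#' @return object of class `scaling_field`: `ratio` (3-D array, 1 outside
#'   the mask), `valid_mask`, `filter_mm`, `n_template`, `modality`,
#'   `voxel_mm`.
#' @export
estimate_scaling <- function(imgs_8ch, imgs_32ch, voxel_mm = NULL,
                             filter_mm = 5, floor_frac = 0.05,
                             modality = "t1") {
  if (length(imgs_8ch) < 2 || length(imgs_8ch) != length(imgs_32ch))
    stop("need >= 2 template subjects with paired images")
  if (is.null(voxel_mm)) voxel_mm <- voxel_size(imgs_8ch[[1]])
  gs <- dim(imgs_8ch[[1]])
  mean_of <- function(lst) Reduce(`+`, lapply(lst, as.numeric)) / length(lst)
  m8 <- array(mean_of(imgs_8ch), gs)
  m32 <- array(mean_of(imgs_32ch), gs)
  floor_val <- floor_frac * stats::quantile(m8, 0.99, names = FALSE)
  valid <- m8 > floor_val
  if (!any(valid)) stop("8CH mean image below the floor everywhere")
  ratio <- array(1, gs)
  ratio[valid] <- m32[valid] / m8[valid]
  if (filter_mm > 0) {
    w <- max(1L, as.integer(round(filter_mm / voxel_mm)))
    if (w %% 2L == 0L) w <- w + 1L       # nearest odd window
    r <- (w - 1L) %/% 2L
    if (r >= 1L)
      ratio <- array(cpp_median_filter3(as.numeric(ratio), as.logical(valid),
                                        as.integer(gs), r), gs)
  }
  ratio[!valid] <- 1
  structure(list(ratio = as_volume(ratio, voxel_mm), valid_mask = valid,
                 filter_mm = filter_mm, n_template = length(imgs_8ch),
                 modality = modality, voxel_mm = voxel_mm),
            class = "scaling_field")
}

#' Apply a scaling field to an 8CH image
#'
#' Voxelwise multiplication by the ratio (identity outside the valid mask,
#' where the ratio is 1).
#'
#' @param image_8ch 3-D array on the field's grid.
#' @param field a `scaling_field`.
#' @param modality modality of `image_8ch`; must match the field's label
#'   (a T1-derived field is never silently applied to DWI or BOLD data).
#' @return scaled 3-D array.
#' @export
apply_scaling <- function(image_8ch, field, modality = field$modality) {
  stopifnot(inherits(field, "scaling_field"))
  if (!identical(dim(image_8ch), dim(field$ratio)))
    stop("image and scaling field are on different grids")
  if (!identical(modality, field$modality))
    stop("modality mismatch: field is for '", field$modality,
         "', image is '", modality, "'")
  as_volume(array(as.numeric(image_8ch) * as.numeric(field$ratio),
                  dim(image_8ch)), field$voxel_mm)
}

#' Validate a scaling field on held-out subjects
#'
#' Re-runs the paired permutation inference on the validation pairs before
#' and after multiplying the 8CH images by the scaling field.
#'
#' @param imgs_8ch,imgs_32ch subject-aligned image lists from the
#'   validation set.
#' @param field a `scaling_field` estimated on the (disjoint) template set.
#' @param mask analysis mask for the inference.
#' @param template_ids,validation_ids optional subject-id vectors; if both
#'   are given they must be disjoint (leakage guard).
#' @param n_perm,seed,alpha,tfce_params passed to [permutation_fwe()].
#' @return list of class `harmonization_report`: `pre`, `post` (each a
#'   `paired_stat_result`), `summary` data frame with significant-voxel
#'   counts and effect sizes per direction.
#' @export
validate_harmonization <- function(imgs_8ch, imgs_32ch, field, mask,
                                   template_ids = NULL, validation_ids = NULL,
                                   n_perm = 1000, seed = 1L, alpha = 0.05,
                                   tfce_params = default_tfce_params()) {
  if (!is.null(template_ids) && !is.null(validation_ids) &&
      length(intersect(template_ids, validation_ids)) > 0)
    stop("template and validation sets overlap: ",
         paste(intersect(template_ids, validation_ids), collapse = ", "))
  scaled <- lapply(imgs_8ch, apply_scaling, field = field)
  pre <- permutation_fwe(imgs_8ch, imgs_32ch, mask, n_perm = n_perm,
                         seed = seed, alpha = alpha, tfce_params = tfce_params)
  post <- permutation_fwe(scaled, imgs_32ch, mask, n_perm = n_perm,
                          seed = seed, alpha = alpha, tfce_params = tfce_params)
  summary <- data.frame(
    stage = rep(c("pre", "post"), each = 2),
    direction = rep(c("positive", "negative"), 2),
    n_sig_voxels = c(sum(pre$sig_mask_pos), sum(pre$sig_mask_neg),
                     sum(post$sig_mask_pos), sum(post$sig_mask_neg)),
    effect_size = c(pre$effect_size_pos, pre$effect_size_neg,
                    post$effect_size_pos, post$effect_size_neg),
    pct_change = c(pre$pct_change_pos, pre$pct_change_neg,
                   post$pct_change_pos, post$pct_change_neg)
  )
  structure(list(pre = pre, post = post, summary = summary),
            class = "harmonization_report")
}

#' Write a scaling field as NIfTI + YAML sidecar
#'
#' @param field a `scaling_field`.
#' @param prefix output path prefix; writes `<prefix>_ratio.nii.gz`,
#'   `<prefix>_valid.nii.gz`, `<prefix>.yaml`.
#' @export
write_scaling_field <- function(field, prefix) {
  write_volume(field$ratio, paste0(prefix, "_ratio.nii.gz"))
  write_volume(array(as.numeric(field$valid_mask), dim(field$ratio)),
               paste0(prefix, "_valid.nii.gz"), voxel_mm = field$voxel_mm)
  yaml::write_yaml(list(modality = field$modality, filter_mm = field$filter_mm,
                        n_template = field$n_template,
                        voxel_mm = field$voxel_mm),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' Read a scaling field written by [write_scaling_field()]
#'
#' @param prefix path prefix used at writing time.
#' @return a `scaling_field`.
#' @export
read_scaling_field <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  ratio <- read_volume(paste0(prefix, "_ratio.nii.gz"))
  valid <- read_volume(paste0(prefix, "_valid.nii.gz")) > 0.5
  structure(list(ratio = ratio, valid_mask = valid,
                 filter_mm = meta$filter_mm, n_template = meta$n_template,
                 modality = meta$modality, voxel_mm = meta$voxel_mm),
            class = "scaling_field")
}
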