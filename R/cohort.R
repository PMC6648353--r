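## Cohort generation: per-subject paired acquisitions under both coil
## profiles, all derived from the same per-subject phantom; only gain,
## noise realization and configurable injected coil effects differ between
## the two acquisitions of a subject.

#' Cohort simulation configuration
#'
#' @param grid_shape,voxel_mm shared acquisition grid (default 32^3 at 6 mm,
#'   a 192 mm field of view).
#' @param modalities subset of `c("t1", "dwi", "bold")` to simulate.
#' @param coil_params list with optional `eight_ch` / `thirty_two_ch`
#'   parameter overrides for [make_coil_profile()].
#' @param contrast_shift named numeric: fractional GM/WM contrast shift
#'   injected per coil (the mechanism by which a coil alters segmentation).
#' @param dwi list: `n_dir`, `bval`, `n_b0`, per-coil `noise_scale`, and
#'   optional `md_bias = list(coil, side, factor)` multiplying the diffusion
#'   tensor on one hemisphere for one coil (off by default).
#' @param bold list: `n_volumes`, `tr_s`, `amplitudes` (one per network),
#'   `nuisance_amplitude`.
#' @param age_range uniform age range for simulated subjects.
#' @param null_pair if `TRUE`, both "coils" use the 8-channel profile, so
#'   the two acquisitions of a subject are exchangeable (a null cohort).
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(grid_shape = c(32, 32, 32), voxel_mm = 6,
                          modalities = c("t1", "dwi", "bold"),
                          coil_params = list(),
                          contrast_shift = c(eight_ch = 0, thirty_two_ch = 0),
                          dwi = list(),
                          bold = list(),
                          age_range = c(45, 80),
                          null_pair = FALSE) {
  dwi <- utils::modifyList(list(n_dir = 60, bval = 1000, n_b0 = 1,
                                noise_scale = c(eight_ch = 1, thirty_two_ch = 1),
                                md_bias = NULL), dwi)
  bold <- utils::modifyList(list(n_volumes = 200, tr_s = 2.2,
                                 amplitudes = rep(1, 8),
                                 nuisance_amplitude = 0.5), bold)
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 modalities = modalities, coil_params = coil_params,
                 contrast_shift = contrast_shift, dwi = dwi, bold = bold,
                 age_range = age_range, null_pair = null_pair),
            class = "cohort_config")
}

## Apply a hemispheric multiplicative bias to a tensor truth (injected
## ground-truth coil effect; never active by default).
apply_md_bias <- function(truth, side, factor) {
  gs <- dim(truth$s0)
  g <- coord_grids(gs)
  hemi <- if (side == "left") g$x < 0.5 else g$x >= 0.5
  scale <- ifelse(hemi, factor, 1)
  d <- matrix(truth$d, ncol = 6L) * as.vector(scale)
  truth$d <- array(d, dim = c(gs, 6L))
  truth
}

simulate_subject <- function(id, age, sex, config, coils, scheme, seed) {
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 8L))
  ph <- make_tissue_phantom(config$grid_shape, config$voxel_mm,
                            seed = sub_seeds[1])
  out <- list(subject_id = id, age = age, sex = sex, phantom = ph)
  kinds <- names(coils)
  if ("t1" %in% config$modalities) {
    for (i in seq_along(kinds)) {
      k <- kinds[i]
      shift <- config$contrast_shift[[coils[[k]]$kind]] %||% 0
      out[[paste0("t1_", short_kind(k))]] <-
        simulate_t1(ph, coils[[k]], contrast_shift = shift,
                    seed = sub_seeds[1 + i])
    }
  }
  if ("dwi" %in% config$modalities) {
    truth <- make_tensor_truth(ph)
    out$tensor_truth <- truth
    for (i in seq_along(kinds)) {
      k <- kinds[i]
      tt <- truth
      mb <- config$dwi$md_bias
      if (!is.null(mb) && identical(mb$coil, coils[[k]]$kind))
        tt <- apply_md_bias(tt, mb$side, mb$factor)
      out[[paste0("dwi_", short_kind(k))]] <-
        simulate_dwi(ph, tt, scheme, coils[[k]],
                     noise_scale = config$dwi$noise_scale[[coils[[k]]$kind]] %||% 1,
                     seed = sub_seeds[3 + i])
    }
  }
  if ("bold" %in% config$modalities) {
    tmpl <- make_network_templates(ph)
    for (i in seq_along(kinds)) {
      k <- kinds[i]
      out[[paste0("bold_", short_kind(k))]] <-
        simulate_bold(ph, tmpl, config$bold$amplitudes, coils[[k]],
                      n_volumes = config$bold$n_volumes,
                      tr_s = config$bold$tr_s,
                      nuisance_amplitude = config$bold$nuisance_amplitude,
                      seed = sub_seeds[5 + i])
    }
  }
  structure(out, class = "subject_pair")
}

short_kind <- function(slot) if (slot == "a") "8ch" else "32ch"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a paired-coil cohort
#'
#' Generates `n_subjects` subjects with randomized ages/sexes and jittered
#' phantom shapes; each subject is "scanned" under both coil profiles for
#' every requested modality. Identical seed and config reproduce the cohort
#' exactly.
#'
#' @param n_subjects at least 2.
#' @param config a [cohort_config()].
#' @param seed master RNG seed; all per-subject seeds derive from it.
#' @param out_dir if given, volumes are written as NIfTI-1 under
#'   `out_dir/sub-*/` with a YAML manifest, and subjects carry file paths
#'   instead of in-memory arrays (use for large cohorts).
#' @return object of class `coil_cohort`: `subjects` (list of
#'   `subject_pair`), `coils` (list `a` = 8CH, `b` = 32CH), `scheme`,
#'   `config`, `seed`, and `manifest` when written to disk.
#' @export
make_cohort <- function(n_subjects, config = cohort_config(), seed = 1L,
                        out_dir = NULL) {
  stopifnot(n_subjects >= 2)
  kinds <- if (isTRUE(config$null_pair)) c("eight_ch", "eight_ch") else
    c("eight_ch", "thirty_two_ch")
  coils <- list(
    a = make_coil_profile(kinds[1], config$grid_shape, config$voxel_mm,
                          params = config$coil_params[[kinds[1]]] %||% list()),
    b = make_coil_profile(kinds[2], config$grid_shape, config$voxel_mm,
                          params = config$coil_params[[kinds[2]]] %||% list())
  )
  scheme <- if ("dwi" %in% config$modalities)
    diffusion_scheme(config$dwi$n_dir, config$dwi$bval, config$dwi$n_b0) else NULL

  meta <- with_seed(seed, list(
    ages = round(runif(n_subjects, config$age_range[1], config$age_range[2]), 1),
    sexes = sample(c("F", "M"), n_subjects, replace = TRUE),
    seeds = sample.int(.Machine$integer.max - 1L, n_subjects)
  ))

  to_disk <- !is.null(out_dir)
  if (to_disk) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  image_slots <- c(outer(c("t1_", "dwi_", "bold_"), c("8ch", "32ch"), paste0))

  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    id <- sprintf("sub-%03d", s)
    sub <- simulate_subject(id, meta$ages[s], meta$sexes[s], config, coils,
                            scheme, meta$seeds[s])
    if (to_disk) {
      sdir <- file.path(out_dir, id)
      dir.create(sdir, showWarnings = FALSE)
      for (slot in intersect(image_slots, names(sub))) {
        p <- file.path(sdir, paste0(slot, ".nii.gz"))
        write_volume(sub[[slot]], p)
        sub[[slot]] <- p
      }
      sub$phantom <- NULL
      sub$tensor_truth <- NULL
    }
    subjects[[s]] <- sub
  }

  cohort <- structure(list(subjects = subjects, coils = coils, scheme = scheme,
                           config = config, seed = seed), class = "coil_cohort")
  if (to_disk) {
    if (!is.null(scheme))
      write_scheme(scheme, file.path(out_dir, "dwi.bval"),
                   file.path(out_dir, "dwi.bvec"))
    man <- list(
      n_subjects = n_subjects, seed = seed,
      config = unclass_config(config),
      subjects = lapply(subjects, function(su) {
        fields <- su[intersect(c("subject_id", "age", "sex", image_slots),
                               names(su))]
        fields
      })
    )
    manifest_path <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(man, manifest_path)
    cohort$manifest <- manifest_path
  }
  cohort
}

unclass_config <- function(config) {
  cf <- unclass(config)
  cf$contrast_shift <- as.list(cf$contrast_shift)
  cf
}

#' Extract one modality's paired image lists from a cohort
#'
#' @param cohort a `coil_cohort`.
#' @param modality `"t1"`, `"dwi"`, or `"bold"`.
#' @return list with `a` (8CH) and `b` (32CH) lists of arrays, loading from
#'   disk if the cohort was written out.
#' @export
cohort_images <- function(cohort, modality = "t1") {
  get_img <- function(su, slot) {
    x <- su[[slot]]
    if (is.character(x)) read_volume(x) else x
  }
  list(a = lapply(cohort$subjects, get_img, paste0(modality, "_8ch")),
       b = lapply(cohort$subjects, get_img, paste0(modality, "_32ch")))
}

#' @export
print.coil_cohort <- function(x, ...) {
  cat("coil_cohort:", length(x$subjects), "subjects,",
      paste(x$config$modalities, collapse = "/"), "on",
      paste(x$config$grid_shape, collapse = "x"), "@",
      x$config$voxel_mm, "mm\n")
  invisible(x)
}
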