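## End-to-end experiment orchestration: simulate a paired cohort, run the
## per-modality analyses, paired inference, harmonization and validation,
## and write machine-readable results with the config hash and seed stamped
## on every output.

#' Experiment configuration
#'
#' @param n_subjects cohort size.
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param cohort a [cohort_config()]; its `modalities` entry decides which
#'   analysis stages run.
#' @param stats list: `n_perm`, `alpha`, `tfce` (TFCE parameter list).
#' @param harmonize list: `filter_mm`, `n_template` (default: half the
#'   cohort, rounded up), `floor_frac`.
#' @param vbm list: `sigma_mm` smoothing for GM/WM maps.
#' @param out_dir output directory.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_subjects = 12, seed = 1L,
                              cohort = cohort_config(modalities = "t1"),
                              stats = list(),
                              harmonize = list(),
                              vbm = list(),
                              out_dir = tempfile("coilbias_run_")) {
  stats <- utils::modifyList(list(n_perm = 500, alpha = 0.05,
                                  tfce = default_tfce_params()), stats)
  harmonize <- utils::modifyList(list(filter_mm = 5, n_template = NULL,
                                      floor_frac = 0.05), harmonize)
  vbm <- utils::modifyList(list(sigma_mm = 3), vbm)
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 cohort = cohort, stats = stats, harmonize = harmonize,
                 vbm = vbm, out_dir = out_dir),
            class = "experiment_config")
}

#' Read / write an experiment config as YAML
#'
#' @param config an `experiment_config`.
#' @param path YAML file path.
#' @return `read_experiment_config` returns an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  cf <- unclass(config)
  cf$cohort <- unclass_config(cf$cohort)
  yaml::write_yaml(cf, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  cf <- yaml::read_yaml(path)
  co <- cf$cohort
  co$contrast_shift <- unlist(co$contrast_shift)
  cohort <- do.call(cohort_config, co[intersect(names(co),
    names(formals(cohort_config)))])
  experiment_config(n_subjects = cf$n_subjects, seed = cf$seed,
                    cohort = cohort, stats = cf$stats,
                    harmonize = cf$harmonize, vbm = cf$vbm,
                    out_dir = cf$out_dir)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # canonical YAML text, so equal configs hash equally regardless of the
  # storage mode (integer vs double, named vector vs list) they arrived in
  writeLines(yaml::as.yaml(unclass_experiment(config), precision = 12), f)
  unname(tools::md5sum(f))
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  lapply(x[!vapply(x, is.null, logical(1))], drop_nulls)
}

unclass_experiment <- function(config) {
  cf <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  cf$out_dir <- NULL  # hash covers the science, not the destination
  # canonicalize storage modes (integer vs double, absent vs NULL) so a
  # YAML round trip hashes identically
  rapply(drop_nulls(cf), function(x) if (is.numeric(x)) as.numeric(x) else x,
         how = "replace")
}

stage_seed <- function(seed, k) (seed * 7919L + k * 104729L) %% 2000000000L

#' Run a full paired-coil experiment
#'
#' Simulates the cohort, runs SNR mapping, the modality analyses configured
#' in the cohort (`t1` -> VBM GM/WM maps, `dwi` -> FA maps in the FA >= 0.2
#' mask, `bold` -> dual-regression z-maps of the medial visual network),
#' paired TFCE/FWE inference per modality, then T1 scaling-factor
#' harmonization on a matched split with validation. Any stage failure
#' aborts with the stage name; outputs written so far are preserved.
#'
#' @param config an [experiment_config()].
#' @return list of class `experiment_report`: `results` (data frame, also
#'   written as `results.csv`), `stats` (per-modality
#'   `paired_stat_result`s), `harmonization` (a `harmonization_report`),
#'   `snr`, `config_hash`, `out_dir`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = file.path(config$out_dir, "run.log"), append = TRUE)
  }
  run_stage <- function(name, expr) {
    log_line("stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs in ", config$out_dir, ")", call. = FALSE))
  }

  results <- list()
  add_result <- function(stage, metric, value)
    results[[length(results) + 1L]] <<- data.frame(
      stage = stage, metric = metric, value = value,
      seed = seed, config_hash = hash)

  cohort <- run_stage("simulate",
    make_cohort(config$n_subjects, config$cohort, seed = seed))
  mods <- config$cohort$modalities
  mask <- phantom_mask(make_tissue_phantom(config$cohort$grid_shape,
                                           config$cohort$voxel_mm, seed = 0L))
  stats_out <- list()

  snr_summary <- run_stage("snr", {
    slice_dim <- c(128L, 128L)
    per_coil <- lapply(c("eight_ch", "thirty_two_ch"), function(kind) {
      cp <- make_coil_profile(kind, slice_dim, voxel_mm = 1.7,
                              params = config$cohort$coil_params[[kind]] %||% list())
      sl <- simulate_snr_slices(cp, seed = stage_seed(seed, 1L))
      snr_map(sl$signal, sl$noise, roi_size = 16)
    })
    names(per_coil) <- c("snr_8ch", "snr_32ch")
    for (nm in names(per_coil)) {
      write_snr_csv(per_coil[[nm]], file.path(config$out_dir,
                                              paste0(nm, ".csv")))
      rm <- per_coil[[nm]]$region_means
      add_result("snr", paste0(nm, "_anterior"), rm[["anterior"]])
      add_result("snr", paste0(nm, "_central"), rm[["central"]])
      add_result("snr", paste0(nm, "_posterior"), rm[["posterior"]])
    }
    per_coil
  })

  maps <- list()
  if ("t1" %in% mods) {
    maps$gm <- run_stage("vbm", {
      imgs <- cohort_images(cohort, "t1")
      seg <- lapply(c("a", "b"), function(cc) lapply(seq_along(imgs[[cc]]),
        function(s) vbm_preprocess(imgs[[cc]][[s]], mask,
                                   sigma_mm = config$vbm$sigma_mm,
                                   seed = stage_seed(seed, s))))
      names(seg) <- c("a", "b")
      maps$wm <- list(a = lapply(seg$a, `[[`, "wm_smoothed"),
                       b = lapply(seg$b, `[[`, "wm_smoothed"))
      list(a = lapply(seg$a, `[[`, "gm_smoothed"),
           b = lapply(seg$b, `[[`, "gm_smoothed"))
    })
  }
  if ("dwi" %in% mods) {
    run_stage("dti", {
      imgs <- cohort_images(cohort, "dwi")
      fits <- lapply(c("a", "b"), function(cc)
        lapply(imgs[[cc]], fit_tensor, scheme = cohort$scheme, mask = mask))
      names(fits) <- c("a", "b")
      fa <- list(a = lapply(fits$a, `[[`, "fa"), b = lapply(fits$b, `[[`, "fa"))
      mean_fa <- Reduce(`+`, c(fa$a, fa$b)) / (2 * length(fa$a))
      fa_mask <- analysis_mask(mean_fa, 0.2)
      maps$fa <- fa
      attr(maps$fa, "mask") <- fa_mask & mask
      invisible(NULL)
    })
  }
  if ("bold" %in% mods) {
    maps$rsfmri <- run_stage("rsfmri", {
      imgs <- cohort_images(cohort, "bold")
      tmpl_ph <- make_tissue_phantom(config$cohort$grid_shape,
                                     config$cohort$voxel_mm, seed = 0L)
      tmpl <- make_network_templates(tmpl_ph)
      zmap <- function(series) rsfmri_connectivity(
        series, tmpl, tr_s = config$cohort$bold$tr_s)$z_maps$medial_visual
      list(a = lapply(imgs$a, zmap), b = lapply(imgs$b, zmap))
    })
  }

  for (nm in names(maps)) {
    m <- maps[[nm]]
    use_mask <- attr(maps[[nm]], "mask") %||% mask
    if (!any(use_mask)) next
    stats_out[[nm]] <- run_stage(paste0("stats_", nm),
      permutation_fwe(m$a, m$b, use_mask, n_perm = config$stats$n_perm,
                      seed = stage_seed(seed, 11L), alpha = config$stats$alpha,
                      tfce_params = config$stats$tfce))
    r <- stats_out[[nm]]
    write_stats_summary(r, file.path(config$out_dir,
                                     paste0("stats_", nm, ".csv")))
    add_result(paste0("stats_", nm), "n_sig_pos", sum(r$sig_mask_pos))
    add_result(paste0("stats_", nm), "n_sig_neg", sum(r$sig_mask_neg))
    add_result(paste0("stats_", nm), "pct_change_pos", r$pct_change_pos)
    add_result(paste0("stats_", nm), "pct_change_neg", r$pct_change_neg)
  }

  harmon <- NULL
  if ("t1" %in% mods) {
    harmon <- run_stage("harmonize", {
      n_tmpl <- config$harmonize$n_template %||%
        ceiling(config$n_subjects / 2)
      split <- split_cohort(cohort, n_tmpl, seed = stage_seed(seed, 21L))
      imgs <- cohort_images(cohort, "t1")
      field <- estimate_scaling(imgs$a[split$template], imgs$b[split$template],
                                voxel_mm = config$cohort$voxel_mm,
                                filter_mm = config$harmonize$filter_mm,
                                floor_frac = config$harmonize$floor_frac,
                                modality = "t1")
      write_scaling_field(field, file.path(config$out_dir, "scaling_t1"))
      rep <- validate_harmonization(
        imgs$a[split$validation], imgs$b[split$validation], field, mask,
        template_ids = split$template, validation_ids = split$validation,
        n_perm = config$stats$n_perm, seed = stage_seed(seed, 22L),
        alpha = config$stats$alpha, tfce_params = config$stats$tfce)
      for (i in seq_len(nrow(rep$summary)))
        add_result("harmonize",
                   paste0(rep$summary$stage[i], "_sig_",
                          rep$summary$direction[i]),
                   rep$summary$n_sig_voxels[i])
      rep
    })
  }

  results <- do.call(rbind, results)
  utils::write.csv(results, file.path(config$out_dir, "results.csv"),
                   row.names = FALSE)
  writeLines(c(
    paste("coilbias experiment, seed", seed, "config", hash),
    paste("subjects:", config$n_subjects, "; modalities:",
          paste(mods, collapse = ", ")),
    utils::capture.output(print(results))
  ), file.path(config$out_dir, "summary.txt"))
  log_line("done")

  structure(list(results = results, stats = stats_out,
                 harmonization = harmon, snr = snr_summary,
                 config_hash = hash, out_dir = config$out_dir),
            class = "experiment_report")
}
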