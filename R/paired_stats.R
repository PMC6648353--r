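## Paired-design inference: within-subject paired t-maps, threshold-free
## cluster enhancement (TFCE), and family-wise error control by the
## permutation distribution of the maximum TFCE statistic under random
## sign-flips of the per-subject difference maps. With n subjects the
## paired design is equivalent to a one-sample test on differences, whose
## exact permutation group is the 2^n sign patterns; when 2^n <= n_perm the
## group is enumerated in full instead of sampled.

default_tfce_params <- function() {
  list(h = 2.0, e = 0.5, n_steps = 100L, connectivity = 26L)
}

## Stack a list of 3-D maps into an (n_mask x n_subjects) matrix.
stack_masked <- function(maps, mask_idx) {
  vapply(maps, function(m) as.numeric(m)[mask_idx], numeric(length(mask_idx)))
}

#' Voxelwise paired t-map
#'
#' Per voxel, with differences `d_i = b_i - a_i` over subjects,
#' `t = mean(d) / (sd(d) / sqrt(n))`, df = n - 1. Voxels with zero
#' difference variance get t = 0.
#'
#' @param maps_a,maps_b subject-aligned lists of 3-D arrays (condition A =
#'   baseline/8CH, condition B = 32CH).
#' @param mask logical array; statistics are computed inside it.
#' @return 3-D array of t values (0 outside the mask), with attributes
#'   `df` and `zero_variance` (logical array flagging degenerate voxels).
#' @export
paired_t <- function(maps_a, maps_b, mask) {
  n <- length(maps_a)
  if (length(maps_b) != n) stop("unequal subject counts")
  if (n < 3) stop("need at least 3 subjects")
  gs <- dim(maps_a[[1]])
  stopifnot(identical(dim(mask), gs))
  idx <- which(as.vector(mask))
  D <- stack_masked(maps_b, idx) - stack_masked(maps_a, idx)
  m <- rowMeans(D)
  v <- rowSums((D - m)^2) / (n - 1)
  # guard against rounding residue when all differences are equal
  zero <- v <= 1e-24 + 1e-20 * m^2
  tvals <- ifelse(zero, 0, m / sqrt(v / n))
  out <- array(0, dim = gs)
  out[idx] <- tvals
  zv <- array(FALSE, dim = gs)
  zv[idx] <- zero
  attr(out, "df") <- n - 1L
  attr(out, "zero_variance") <- zv
  out
}

#' Threshold-free cluster enhancement of a statistic map
#'
#' `TFCE(v) = sum_h extent(h, v)^E * h^H * dh` over `n_steps` thresholds
#' from `dh` to `max(stat)` (`dh = max(stat) / n_steps`), where
#' `extent(h, v)` is the size of the connected component containing `v` in
#' the supra-threshold set at `h`. Only positive values are enhanced; run
#' on the negated map for the negative direction.
#'
#' @param stat_map 3-D array (e.g. a t-map).
#' @param mask non-empty logical array.
#' @param h height exponent H (default 2).
#' @param e extent exponent E (default 0.5).
#' @param n_steps number of threshold steps (>= 10; the step size adapts to
#'   the map maximum).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return 3-D array of TFCE scores (>= 0; 0 wherever `stat_map <= 0`).
#' @export
tfce <- function(stat_map, mask, h = 2.0, e = 0.5, n_steps = 100,
                 connectivity = 26) {
  if (!any(mask)) stop("mask is empty")
  if (n_steps < 10) stop("n_steps must be at least 10")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  gs <- dim(stat_map)
  stopifnot(identical(dim(mask), gs))
  out <- cpp_tfce(as.numeric(stat_map), as.logical(mask), as.integer(gs),
                  h, e, as.integer(n_steps), as.integer(connectivity))
  array(out, dim = gs)
}

## Sign matrix for the permutation null: full enumeration when feasible,
## otherwise the observed labeling plus random draws.
sign_matrix <- function(n_sub, n_perm, seed) {
  if (2^n_sub <= n_perm) {
    combos <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n_sub)))
    t(combos[, n_sub:1, drop = FALSE])  # n_sub x 2^n, observed (+1...) first
  } else {
    with_seed(seed, {
      s <- matrix(sample(c(1L, -1L), n_sub * (n_perm - 1), replace = TRUE),
                  nrow = n_sub)
      cbind(rep(1L, n_sub), s)
    })
  }
}

#' Paired permutation inference with TFCE and FWE correction
#'
#' Runs the full inference chain: paired t-map, TFCE in both directions,
#' and family-wise-error-corrected p-values from the sign-flip permutation
#' distribution of the maximum TFCE statistic (the observed labeling is
#' always included in the null). For n subjects with `2^n <= n_perm` the
#' sign-flip group is enumerated exactly, so results are seed-independent.
#'
#' @param maps_a,maps_b subject-aligned lists of 3-D arrays (A = 8CH
#'   baseline, B = 32CH).
#' @param mask logical analysis mask.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed (mandatory when sampling).
#' @param alpha significance level (default 0.05).
#' @param tfce_params list `h`, `e`, `n_steps`, `connectivity`.
#' @return object of class `paired_stat_result`: `t_map`, `tfce_pos`,
#'   `tfce_neg`, `p_fwe_pos`, `p_fwe_neg`, `sig_mask_pos`, `sig_mask_neg`,
#'   `effect_size_pos/neg`, `pct_change_pos/neg` (over the respective
#'   significant voxels; `NA` when empty), `null_max` (n_perm x 2),
#'   `n_permutations`, `exhaustive`, `alpha`, `seed`, `tfce_params`.
#' @export
permutation_fwe <- function(maps_a, maps_b, mask, n_perm = 5000, seed = NULL,
                            alpha = 0.05, tfce_params = default_tfce_params()) {
  n <- length(maps_a)
  if (length(maps_b) != n) stop("unequal subject counts")
  if (n < 3) stop("need at least 3 subjects")
  tp <- utils::modifyList(default_tfce_params(), tfce_params)
  exhaustive <- 2^n <= n_perm
  if (!exhaustive && is.null(seed))
    stop("seed is mandatory for sampled permutations")
  if (n_perm < 100) warning("fewer than 100 permutations; p-values are coarse")
  gs <- dim(maps_a[[1]])
  stopifnot(identical(dim(mask), gs))
  idx <- which(as.vector(mask))
  D <- stack_masked(maps_b, idx) - stack_masked(maps_a, idx)

  signs <- sign_matrix(n, n_perm, seed)
  perm <- cpp_perm_null_max(D, signs, as.integer(gs),
                            as.integer(idx - 1L), tp$h, tp$e,
                            as.integer(tp$n_steps),
                            as.integer(tp$connectivity))
  null_max <- perm$max
  # observed maps come from the first (identity) permutation, so they share
  # the null distribution's arithmetic exactly
  t_map <- array(perm$t_obs, dim = gs)
  attr(t_map, "df") <- n - 1L
  tf_pos <- array(perm$tfce_pos, dim = gs)
  tf_neg <- array(perm$tfce_neg, dim = gs)

  pmap <- function(tf, null_col) {
    p <- array(1, dim = gs)
    p[idx] <- vapply(as.numeric(tf)[idx], function(x) mean(null_col >= x),
                     numeric(1))
    p
  }
  p_pos <- pmap(tf_pos, null_max[, 1])
  p_neg <- pmap(tf_neg, null_max[, 2])
  sig_pos <- (p_pos < alpha) & mask & tf_pos > 0
  sig_neg <- (p_neg < alpha) & mask & tf_neg > 0

  eff_pos <- summarize_effect(maps_a, maps_b, sig_pos)
  eff_neg <- summarize_effect(maps_a, maps_b, sig_neg)

  structure(list(
    t_map = t_map, tfce_pos = tf_pos, tfce_neg = tf_neg,
    p_fwe_pos = p_pos, p_fwe_neg = p_neg,
    sig_mask_pos = sig_pos, sig_mask_neg = sig_neg,
    effect_size_pos = eff_pos$effect_size, pct_change_pos = eff_pos$pct_change,
    effect_size_neg = eff_neg$effect_size, pct_change_neg = eff_neg$pct_change,
    null_max = null_max, n_permutations = ncol(signs),
    exhaustive = exhaustive, alpha = alpha, seed = seed, tfce_params = tp
  ), class = "paired_stat_result")
}

#' Effect size and percent change over a voxel set
#'
#' Pools the voxels in `sig_mask`: each subject contributes its mean value
#' over the mask; the paired Cohen's d is `mean(d) / sd(d)` of the
#' per-subject mean differences, and percent change is
#' `100 * (mean_b - mean_a) / mean_a` (condition A, the 8CH baseline, is
#' the denominator).
#'
#' @param maps_a,maps_b subject-aligned lists of 3-D arrays.
#' @param sig_mask logical array of voxels to pool.
#' @return list `effect_size`, `pct_change`, `n_voxels`, `degenerate`
#'   (`TRUE` when the difference SD is zero, effect size +/-Inf). Empty
#'   mask gives `NA` values.
#' @export
summarize_effect <- function(maps_a, maps_b, sig_mask) {
  idx <- which(as.vector(sig_mask))
  if (length(idx) == 0)
    return(list(effect_size = NA_real_, pct_change = NA_real_,
                n_voxels = 0L, degenerate = FALSE))
  a_sub <- vapply(maps_a, function(m) mean(as.numeric(m)[idx]), numeric(1))
  b_sub <- vapply(maps_b, function(m) mean(as.numeric(m)[idx]), numeric(1))
  d <- b_sub - a_sub
  s <- stats::sd(d)
  degenerate <- s <= 1e-10 * mean(abs(d))
  eff <- if (degenerate) sign(mean(d)) * Inf else mean(d) / s
  pct <- 100 * (mean(b_sub) - mean(a_sub)) / mean(a_sub)
  list(effect_size = eff, pct_change = pct, n_voxels = length(idx),
       degenerate = degenerate)
}

#' @export
print.paired_stat_result <- function(x, ...) {
  cat("paired_stat_result:", x$n_permutations, "permutations",
      if (x$exhaustive) "(exhaustive)" else "(sampled)", "\n")
  cat(sprintf("  positive (B > A): %d sig voxels, d = %.3f, %%change = %.2f\n",
              sum(x$sig_mask_pos), x$effect_size_pos, x$pct_change_pos))
  cat(sprintf("  negative (B < A): %d sig voxels, d = %.3f, %%change = %.2f\n",
              sum(x$sig_mask_neg), x$effect_size_neg, x$pct_change_neg))
  invisible(x)
}

#' Write a paired-stat summary CSV
#'
#' @param result a `paired_stat_result`.
#' @param path output CSV path.
#' @export
write_stats_summary <- function(result, path) {
  df <- data.frame(
    direction = c("positive", "negative"),
    n_sig_voxels = c(sum(result$sig_mask_pos), sum(result$sig_mask_neg)),
    effect_size = c(result$effect_size_pos, result$effect_size_neg),
    pct_change = c(result$pct_change_pos, result$pct_change_neg),
    n_permutations = result$n_permutations,
    alpha = result$alpha
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
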