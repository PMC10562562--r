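#' Conjunctional specificity experiment
#'
#' Generates cohorts in which exactly one representation level (movement,
#' visual or task context) carries signal, runs the three erasing-data
#' decoding analyses on every cohort, and summarizes group-level accuracy
#' and TFCE detections per region. The core guarantee under test: a level's
#' signal is detected (one-sided, above chance) only by its own analysis.
#' Direction-level signals anti-generalize (below chance) in the other
#' direction-level analysis on rotation-rotation pairs — a structural
#' property of cross-classification between the two rotations — so
#' specificity is asserted against spurious above-chance decoding.
#'
#' @param n_subjects Subjects per cohort.
#' @param grid_dims Grid dimensions.
#' @param amplitude Planted signal amplitude (signal units).
#' @param n_perm Permutations for the group TFCE tests.
#' @param analyses Analyses to run on each cohort.
#' @param levels Which single-level cohorts to generate.
#' @return List of class \code{specificity_result}: per planted level, per
#'   analysis, the per-subject whole-map mean accuracy (pp), the mean
#'   accuracy and pooled binomial test in the null region, the mean
#'   accuracy in the planted region, and the count of significant
#'   (p_FWE < 0.05) voxels inside and outside the planted level's region.
#' @export
specificity_experiment <- function(n_subjects = 8, grid_dims = c(24, 24, 18),
                                   amplitude = 0.35, n_perm = 500,
                                   analyses = c("visual", "movement",
                                                "context_rot_rot"),
                                   levels = c("visual", "movement",
                                              "context")) {
  grid <- volume_grid(grid_dims)
  regions <- default_region_masks(grid)
  spheres <- searchlight_spheres(grid, 9)
  own_region <- c(visual = "visual_region", movement = "movement_region",
                  context_rot_rot = "context_region",
                  context_rot_mirror = "context_region")
  own_analysis <- c(visual = "visual", movement = "movement",
                    context = "context_rot_rot")
  out <- list()
  for (lev in levels) {
    amp <- c(visual = 0, movement = 0, context = 0, prep = 0)
    amp[[lev]] <- amplitude
    model <- pattern_model(grid, regions, amplitude = amp,
                           link = link_constant(0.4))
    cohort <- sample_cohort(n_subjects, model)
    for (an in analyses) {
      amaps <- lapply(cohort, run_searchlight_decoding, analysis = an,
                      config = decoding_config(), spheres = spheres)
      maps_raw <- vapply(amaps, `[[`, numeric(sum(grid$mask)), "values")
      n_tests <- amaps[[1]]$n_tests
      maps_sm <- t(apply(maps_raw, 2, function(col) {
        a <- array(0, grid$dims); a[grid$mask] <- col
        smooth_volume(a, 8, grid$voxel_size_mm)[grid$mask]
      }))
      gsm <- permutation_fwe(maps_sm, group_design(n_subjects,
                                                   tested = "intercept"),
                             grid, n_perm = n_perm)
      null_idx <- regions$null_region[grid$mask]
      planted_idx <- regions[[paste0(lev, "_region")]][grid$mask]
      own_idx <- regions[[own_region[[an]]]][grid$mask]
      # pooled binomial check in the signal-free null region: mean
      # accuracy over null-region spheres, converted back to correct
      # counts per subject
      null_acc_pp <- colMeans(maps_raw[null_idx, , drop = FALSE])
      correct <- round((null_acc_pp / 100 + 0.5) * n_tests)
      btest <- stats::binom.test(sum(correct), n_tests * n_subjects, 0.5)
      sig <- gsm$p_fwe < 0.05
      out[[lev]][[an]] <- list(
        map_mean_pp = colMeans(maps_raw),
        null_region_mean_pp = mean(null_acc_pp),
        null_region_binom_p = btest$p.value,
        planted_region_mean_pp = mean(colMeans(maps_raw[planted_idx, ,
                                                        drop = FALSE])),
        own_region_mean_pp = mean(colMeans(maps_raw[own_idx, ,
                                                    drop = FALSE])),
        n_sig_in_own_region = sum(sig & own_idx),
        n_sig_total = sum(sig),
        detected = any(sig & own_idx),
        own_analysis = unname(own_analysis[[lev]]) == an)
    }
  }
  structure(out, class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  for (lev in names(x)) {
    cat("planted level:", lev, "\n")
    for (an in names(x[[lev]])) {
      r <- x[[lev]][[an]]
      cat(sprintf("  %-18s map %6.2f pp | planted region %6.2f pp | sig own/total %d/%d%s\n",
                  an, mean(r$map_mean_pp), r$planted_region_mean_pp,
                  r$n_sig_in_own_region, r$n_sig_total,
                  if (r$own_analysis) "  <- own analysis" else ""))
    }
  }
  invisible(x)
}

#' Accuracy-performance slope recovery experiment
#'
#' The headline parameter-recovery check: cohorts with an increasing
#' performance-to-commonality link must yield a negative slope of
#' context-decoding accuracy (ROI over the planted context region,
#' correlation-analysis variant without folds) on mean rotation
#' performance; cohorts with a flat link must reject at the nominal rate.
#' The slope p-value is a one-sided permutation test of the regression t
#' statistic (covariate shuffling).
#'
#' @param n_replicates Number of seeded cohort replicates.
#' @param link \code{"increasing"} (default affine link) or \code{"flat"}.
#' @param n_subjects Cohort size.
#' @param grid_dims Grid dimensions (the calibration default is a reduced
#'   grid; only the context-region ROI is decoded).
#' @param n_perm Permutations for the slope test.
#' @param flat_rho Commonality used by the flat link.
#' @return Data frame with one row per replicate: \code{slope} (pp per
#'   dots/s) and \code{p}.
#' @export
slope_recovery_experiment <- function(n_replicates = 20,
                                      link = c("increasing", "flat"),
                                      n_subjects = 12,
                                      grid_dims = c(16, 16, 12),
                                      n_perm = 199, flat_rho = 0.55) {
  link <- match.arg(link)
  grid <- volume_grid(grid_dims)
  regions <- default_region_masks(grid)
  model <- pattern_model(grid, regions,
                         link = if (link == "flat") link_constant(flat_rho)
                                else link_affine())
  one <- function() {
    coh <- sample_cohort(n_subjects, model)
    acc <- vapply(coh, function(s)
      as.numeric(roi_decoding(s, regions$context_region, "context_rot_rot",
                              decoding_config(use_folds = FALSE))), 0)
    perf <- vapply(coh, function(s) s$performance$mean_rotation_speed, 0)
    des <- group_design(n_subjects, covariate = perf, tested = "covariate",
                        alternative = "less")
    t_obs <- group_glm_t(matrix(acc, ncol = 1), des)
    null_t <- replicate(n_perm, {
      d2 <- group_design(n_subjects, covariate = sample(perf),
                         tested = "covariate", alternative = "less")
      group_glm_t(matrix(acc, ncol = 1), d2)
    })
    slope <- stats::coef(stats::lm(acc ~ perf))[[2]]
    c(slope = slope, p = (1 + sum(null_t >= t_obs)) / (1 + n_perm))
  }
  res <- t(replicate(n_replicates, one()))
  as.data.frame(res)
}

#' Permutation FWE calibration experiment
#'
#' Under an exchangeable null (i.i.d. Gaussian subject maps), the
#' max-statistic TFCE permutation test must control the family-wise error
#' at or below the nominal level: the fraction of replicates with any
#' voxel at \code{p_fwe < alpha} estimates the attained FWE.
#'
#' @param n_replicates Null replicates.
#' @param n_subjects Subjects per replicate.
#' @param grid_dims Grid dimensions (reduced for calibration).
#' @param n_perm Permutations per test (reduced scale).
#' @param alpha Nominal FWE level.
#' @return List: \code{fwe} (attained rate), \code{rejections} (logical
#'   per replicate), \code{mc_se} (Monte-Carlo standard error at the
#'   nominal level).
#' @export
fwe_calibration_experiment <- function(n_replicates = 150, n_subjects = 10,
                                       grid_dims = c(12, 12, 10),
                                       n_perm = 500, alpha = 0.05) {
  grid <- volume_grid(grid_dims)
  nv <- sum(grid$mask)
  design <- group_design(n_subjects, tested = "intercept")
  rej <- vapply(seq_len(n_replicates), function(r) {
    maps <- matrix(stats::rnorm(n_subjects * nv), n_subjects, nv)
    gsm <- permutation_fwe(maps, design, grid, n_perm = n_perm)
    any(gsm$p_fwe < alpha)
  }, TRUE)
  list(fwe = mean(rej), rejections = rej,
       mc_se = sqrt(alpha * (1 - alpha) / n_replicates))
}
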