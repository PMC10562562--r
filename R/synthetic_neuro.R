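#' Volume grid
#'
#' Common 3-D voxel grid shared by all subjects of a synthetic cohort.
#'
#' @param dims Integer length-3 grid dimensions (voxels).
#' @param voxel_size_mm Isotropic voxel size (mm).
#' @param mask Optional logical array; default is the inscribed ellipsoid
#'   (a crude brain-like support).
#' @return Object of class \code{volume_grid}.
#' @export
volume_grid <- function(dims = c(24, 24, 18), voxel_size_mm = 3, mask = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive integers")
  if (is.null(mask)) {
    ctr <- (dims + 1) / 2
    ax <- dims / 2
    idx <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                       z = seq_len(dims[3]))
    inside <- ((idx$x - ctr[1]) / ax[1])^2 + ((idx$y - ctr[2]) / ax[2])^2 +
      ((idx$z - ctr[3]) / ax[3])^2 <= 1
    mask <- array(inside, dims)
  }
  if (!any(mask)) stop("brain mask is empty")
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm, mask = mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("Volume grid:", paste(x$dims, collapse = " x "), "voxels at",
      x$voxel_size_mm, "mm;", sum(x$mask), "in mask\n")
  invisible(x)
}

# Cube mask of half-width hw around a fractional center position.
.cube_mask <- function(grid, frac_center, hw = 2L) {
  ctr <- round(frac_center * grid$dims)
  m <- array(FALSE, grid$dims)
  rng <- lapply(1:3, function(a)
    max(1L, ctr[a] - hw):min(grid$dims[a], ctr[a] + hw))
  m[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  m & grid$mask
}

#' Default signal-region masks
#'
#' Four disjoint cubic regions inside the brain mask carrying (respectively)
#' visual-direction, movement-direction and task-context signal, plus a
#' signal-free null region.
#'
#' @param grid A [volume_grid()].
#' @param half_width Cube half-width in voxels (5x5x5 regions on the
#'   default grid; shrinks to 3x3x3 on grids too small to keep the four
#'   cubes disjoint).
#' @return Named list of logical arrays: \code{visual_region},
#'   \code{movement_region}, \code{context_region}, \code{null_region}.
#' @export
default_region_masks <- function(grid,
                                 half_width = if (min(grid$dims[1:2]) >= 15)
                                   2L else 1L) {
  list(
    visual_region   = .cube_mask(grid, c(0.33, 0.33, 0.5), half_width),
    movement_region = .cube_mask(grid, c(0.67, 0.33, 0.5), half_width),
    context_region  = .cube_mask(grid, c(0.33, 0.67, 0.5), half_width),
    null_region     = .cube_mask(grid, c(0.67, 0.67, 0.5), half_width)
  )
}

#' Affine performance-to-commonality link
#'
#' Monotone map from behavioral performance (dots/s) to the context-pattern
#' correlation rho, affine then clipped to \code{[lo, hi]}.
#'
#' @param intercept,slope Affine coefficients.
#' @param lo,hi Clipping bounds for rho.
#' @return Function \code{performance -> rho}.
#' @export
link_affine <- function(intercept = -0.98, slope = 0.9, lo = 0, hi = 0.95) {
  force(intercept); force(slope); force(lo); force(hi)
  function(performance) pmin(hi, pmax(lo, intercept + slope * performance))
}

#' @rdname link_affine
#' @param rho Constant commonality value.
#' @export
link_constant <- function(rho = 0.5) {
  force(rho)
  function(performance) rep(rho, length(performance))
}

#' Pattern model for the synthetic cohort
#'
#' Where and how strongly the three representation levels are planted, the
#' voxel noise level, and the link tying per-subject behavioral performance
#' to the cross-context commonality of the context patterns.
#'
#' @param grid A [volume_grid()].
#' @param regions Named region masks (see [default_region_masks()]).
#' @param amplitude Named amplitudes (signal units) for \code{visual},
#'   \code{movement}, \code{context}, \code{prep} patterns.
#' @param noise_sd Voxelwise Gaussian noise sd of each beta volume.
#' @param link Performance-to-rho link function (see [link_affine()]).
#' @param allow_overlap Permit overlapping region masks.
#' @return Object of class \code{pattern_model}.
#' @export
pattern_model <- function(grid = volume_grid(),
                          regions = default_region_masks(grid),
                          amplitude = c(visual = 0.35, movement = 0.35,
                                        context = 0.35, prep = 0.35),
                          noise_sd = 1, link = link_affine(),
                          allow_overlap = FALSE) {
  stopifnot(all(c("visual_region", "movement_region", "context_region",
                  "null_region") %in% names(regions)))
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!allow_overlap) {
    tot <- Reduce(`+`, lapply(regions, function(m) as.integer(m)))
    if (any(tot > 1)) stop("region masks overlap")
  }
  structure(list(grid = grid, regions = regions, amplitude = amplitude,
                 noise_sd = noise_sd, link = link,
                 allow_overlap = allow_overlap), class = "pattern_model")
}

#' Plant two correlated patterns in a mask
#'
#' Gaussian mixing construction: \code{p2 = rho * p1 + sqrt(1 - rho^2) * w}
#' with \code{p1, w} independent standard normal fields scaled by
#' \code{amplitude}, so the population correlation is exactly \code{rho}.
#'
#' @param mask Logical array (or integer count of voxels).
#' @param rho Target correlation, in \code{[-1, 1]}.
#' @param amplitude Pattern scale (signal units).
#' @return List with \code{pattern1} and \code{pattern2}; arrays if
#'   \code{mask} was an array (zeros outside the mask), vectors otherwise.
#' @export
plant_correlated_patterns <- function(mask, rho, amplitude = 1) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  as_array <- is.array(mask)
  n <- if (as_array) sum(mask) else as.integer(mask)
  if (n < 1L) stop("mask is empty")
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  p1 <- amplitude * z1
  p2 <- amplitude * (rho * z1 + sqrt(1 - rho^2) * z2)
  if (!as_array) return(list(pattern1 = p1, pattern2 = p2))
  a1 <- array(0, dim(mask)); a2 <- array(0, dim(mask))
  a1[mask] <- p1; a2[mask] <- p2
  list(pattern1 = a1, pattern2 = a2)
}

# Per-subject latent patterns: one per direction for visual and movement
# regions, one per context (erasing and preparation) in the context region,
# with the rotation pair correlated at rho_rot and the mirror pattern
# correlated with the normalized rotation-family mean at rho_mir.
.draw_subject_patterns <- function(model, rho_rot, rho_mir) {
  nv <- sum(model$regions$visual_region)
  nm <- sum(model$regions$movement_region)
  nc <- sum(model$regions$context_region)
  dirs <- direction_labels()$name
  vis <- lapply(dirs, function(d) stats::rnorm(nv))
  names(vis) <- dirs
  mov <- lapply(dirs, function(d) stats::rnorm(nm))
  names(mov) <- dirs
  draw_ctx <- function() {
    pr <- plant_correlated_patterns(nc, rho_rot)
    fam <- (pr$pattern1 + pr$pattern2) / sqrt(2 + 2 * rho_rot)
    w <- stats::rnorm(nc)
    list(rot_minus90 = pr$pattern1, rot_plus90 = pr$pattern2,
         mirror = rho_mir * fam + sqrt(1 - rho_mir^2) * w)
  }
  list(visual = vis, movement = mov, context = draw_ctx(),
       prep = draw_ctx())
}

#' Beta series container
#'
#' @param grid A [volume_grid()].
#' @param coefficients \code{n_voxels x n_regressors} matrix (in-mask voxel
#'   rows in array order).
#' @param info Data frame with one row per regressor: \code{block},
#'   \code{regressor}, \code{context}, \code{visual_direction},
#'   \code{movement_direction}, \code{rep}.
#' @return Object of class \code{beta_series}.
#' @export
beta_series <- function(grid, coefficients, info) {
  stopifnot(nrow(coefficients) == sum(grid$mask),
            ncol(coefficients) == nrow(info))
  structure(list(grid = grid, coefficients = coefficients, info = info),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat("Beta series:", ncol(x$coefficients), "regressors x",
      nrow(x$coefficients), "in-mask voxels\n")
  print(table(x$info$regressor))
  invisible(x)
}

# Regressor bookkeeping for one session: direction, null and preparation
# regressors per block, with context repetition index by execution order.
.beta_info <- function(session) {
  ctx <- vapply(session$blocks, `[[`, "", "context")
  rep_idx <- stats::ave(seq_along(ctx), ctx, FUN = seq_along)
  dirs <- direction_labels()$name
  regs <- c(dirs, "null", "prep")
  nb <- length(ctx)
  block <- rep(seq_len(nb), each = length(regs))
  regressor <- rep(regs, nb)
  vis <- ifelse(regressor %in% dirs, regressor, NA)
  context <- ctx[block]
  mov <- rep(NA_character_, length(block))
  has_dir <- !is.na(vis)
  mov[has_dir] <- required_movement(context[has_dir], vis[has_dir])
  data.frame(block = block, regressor = regressor, context = context,
             visual_direction = vis, movement_direction = mov,
             rep = rep_idx[block], stringsAsFactors = FALSE)
}

# Direct (fast-path) beta generation: planted patterns plus voxel noise.
.generate_betas <- function(model, session, patterns) {
  grid <- model$grid
  vmask <- grid$mask
  n_vox <- sum(vmask)
  reg_idx <- lapply(model$regions, function(m) which(m[vmask]))
  info <- .beta_info(session)
  amp <- model$amplitude
  B <- matrix(stats::rnorm(n_vox * nrow(info), 0, model$noise_sd),
              n_vox, nrow(info))
  for (j in seq_len(nrow(info))) {
    r <- info[j, ]
    if (r$regressor %in% direction_labels()$name) {
      B[reg_idx$visual_region, j] <- B[reg_idx$visual_region, j] +
        amp[["visual"]] * patterns$visual[[r$visual_direction]]
      B[reg_idx$movement_region, j] <- B[reg_idx$movement_region, j] +
        amp[["movement"]] * patterns$movement[[r$movement_direction]]
      B[reg_idx$context_region, j] <- B[reg_idx$context_region, j] +
        amp[["context"]] * patterns$context[[r$context]]
    } else if (r$regressor == "prep") {
      B[reg_idx$context_region, j] <- B[reg_idx$context_region, j] +
        amp[["prep"]] * patterns$prep[[r$context]]
    }
  }
  beta_series(grid, B, info)
}

#' Sample a synthetic cohort
#'
#' Per subject: a session design, behavioral trials around subject-specific
#' target speeds, a performance summary, commonality values
#' \code{rho = link(performance)} (rotation pair from the rotation mean,
#' rotation-family vs mirror from the mirror mean), and a beta series with
#' the planted visual / movement / context patterns plus voxel noise.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param model A [pattern_model()].
#' @param timing A [timing_params()].
#' @param speed_mean,speed_between_sd Cohort mean and between-subject sd of
#'   the target erasing speeds (dots/s), names \code{rotation},
#'   \code{mirror}.
#' @param behavior \code{"fast"} (statistical trial draw) or
#'   \code{"simulate"} (full trial mechanics).
#' @return List of \code{subject_dataset} objects (class
#'   \code{subject_dataset}: subject_id, session, trials, performance,
#'   rho, betas).
#' @export
sample_cohort <- function(n_subjects, model = pattern_model(),
                          timing = timing_params(),
                          speed_mean = c(rotation = 1.7, mirror = 2.4),
                          speed_between_sd = c(rotation = 0.22, mirror = 0.22),
                          behavior = c("fast", "simulate")) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  behavior <- match.arg(behavior)
  lapply(seq_len(n_subjects), function(s) {
    session <- build_session(timing)
    tgt <- c(
      rotation = max(0.3, stats::rnorm(1, speed_mean[["rotation"]],
                                       speed_between_sd[["rotation"]])),
      mirror = max(0.3, stats::rnorm(1, speed_mean[["mirror"]],
                                     speed_between_sd[["mirror"]])))
    trials <- if (behavior == "fast")
      simulate_subject_behavior_fast(session, tgt)
    else simulate_subject_behavior(session, tgt)
    perf <- summarize_performance(trials)
    rho_rot <- model$link(perf$mean_rotation_speed)
    rho_mir <- model$link(perf$mean_mirror_speed)
    if (abs(rho_rot) > 1 || abs(rho_mir) > 1)
      stop("link produced a rho outside [-1, 1]")
    patterns <- .draw_subject_patterns(model, rho_rot, rho_mir)
    betas <- .generate_betas(model, session, patterns)
    structure(list(subject_id = sprintf("sub-%02d", s), session = session,
                   trials = trials, performance = perf,
                   rho = c(rotation = rho_rot, mirror = rho_mir),
                   betas = betas),
              class = "subject_dataset")
  })
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("Subject", x$subject_id, "- rho(rot) =", round(x$rho[["rotation"]], 3),
      ", rho(mir) =", round(x$rho[["mirror"]], 3), "\n")
  cat("rotation speed", round(x$performance$mean_rotation_speed, 2),
      "dots/s, mirror speed", round(x$performance$mean_mirror_speed, 2),
      "dots/s\n")
  invisible(x)
}

#' Simulate a 4-D BOLD series from planted betas
#'
#' Forward model of the first-level GLM: the MVPA design matrix applied to
#' the planted beta series, plus AR(1) voxel noise and optional motion /
#' global-signal artifacts. Score and termination regressors carry zero
#' signal.
#'
#' @param session A \code{session_design}.
#' @param betas A \code{beta_series} for this session.
#' @param hrf An [hrf_params()].
#' @param noise_sd AR(1) innovation sd (0 for a noiseless series).
#' @param ar_phi AR(1) coefficient.
#' @param motion_sd Random-walk step sd of the six motion parameters.
#' @param fd_spike_scans Scans receiving a 2-mm translation jump.
#' @param global_spike_scans Scans receiving a 6-SD global-signal spike.
#' @param tr Repetition time (s).
#' @return List: \code{bold} (n_scans x n_voxels matrix over in-mask
#'   voxels), \code{nuisance} (data frame: mot1..mot6, global_signal),
#'   \code{design} (the design matrix used), \code{n_scans}.
#' @export
simulate_bold <- function(session, betas, hrf = hrf_params(), noise_sd = 1,
                          ar_phi = 0.3, motion_sd = 0.02,
                          fd_spike_scans = integer(0),
                          global_spike_scans = integer(0),
                          tr = session$timing$tr_s) {
  if (tr != session$timing$tr_s) stop("TR inconsistent with the session events")
  n_scans <- n_scans_for_session(session)
  X <- build_design_matrix(session, trials = NULL, variant = "mvpa",
                           nuisance = NULL, hrf = hrf, n_scans = n_scans,
                           tr = tr)
  info <- betas$info
  colname_of <- ifelse(info$regressor == "prep",
                       sprintf("b%02d_prep", info$block),
                       ifelse(info$regressor == "null",
                              sprintf("b%02d_null", info$block),
                              sprintf("b%02d_%s", info$block, info$regressor)))
  keep <- colname_of %in% colnames(X)
  if (!all(keep)) stop("beta series has regressors absent from the design")
  n_vox <- nrow(betas$coefficients)
  Y <- X[, colname_of, drop = FALSE] %*% t(betas$coefficients)
  if (noise_sd > 0) {
    eps <- matrix(stats::rnorm(n_scans * n_vox, 0, noise_sd), n_scans, n_vox)
    if (ar_phi != 0)
      eps <- apply(eps, 2, function(e)
        as.numeric(stats::filter(e, ar_phi, method = "recursive")))
    Y <- Y + eps
  }
  # translations in mm; rotations in radians (kept small so their 50-mm
  # arc-length contribution to FD matches the translation scale)
  step_sd <- c(rep(motion_sd, 3), rep(motion_sd / 50, 3))
  motion <- apply(matrix(stats::rnorm(n_scans * 6, 0, 1), n_scans, 6) %*%
                    diag(step_sd), 2, cumsum)
  if (length(fd_spike_scans) > 0)
    motion[fd_spike_scans, 1] <- motion[fd_spike_scans, 1] + 2
  gs <- rowMeans(Y)
  if (length(global_spike_scans) > 0) {
    sdg <- max(stats::sd(gs), 1e-8)
    gs[global_spike_scans] <- gs[global_spike_scans] + 6 * sdg
  }
  nuis <- data.frame(matrix(motion, n_scans, 6,
                            dimnames = list(NULL, sprintf("mot%d", 1:6))),
                     global_signal = gs)
  list(bold = Y, nuisance = nuis, design = X, n_scans = n_scans)
}

#' Recover a beta series from a simulated BOLD run
#'
#' Fits the first-level MVPA GLM to a simulated series and extracts the
#' direction, null and preparation betas in the same layout as the planted
#' beta series (the full-path generator; the round-trip counterpart of
#' [simulate_bold()]).
#'
#' @param session A \code{session_design}.
#' @param bold Output of [simulate_bold()].
#' @param grid The cohort [volume_grid()].
#' @param trials Optional trial records for outlier handling.
#' @param hrf An [hrf_params()].
#' @return A \code{beta_series}.
#' @export
fit_beta_series <- function(session, bold, grid, trials = NULL,
                            hrf = hrf_params()) {
  fit <- fit_glm(bold$bold, bold$design)
  info <- .beta_info(session)
  colname_of <- ifelse(info$regressor == "prep",
                       sprintf("b%02d_prep", info$block),
                       ifelse(info$regressor == "null",
                              sprintf("b%02d_null", info$block),
                              sprintf("b%02d_%s", info$block, info$regressor)))
  keep <- colname_of %in% rownames(fit$betas)
  beta_series(grid, unname(t(fit$betas[colname_of[keep], , drop = FALSE])),
              info[keep, ])
}
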