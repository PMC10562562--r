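#' Canonical double-gamma HRF parameters
#'
#' @param peak_delay_s Delay of the response peak (s).
#' @param undershoot_delay_s Delay of the undershoot (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Kernel length (s).
#' @return List of class \code{hrf_params}.
#' @export
hrf_params <- function(peak_delay_s = 6, undershoot_delay_s = 16, ratio = 6,
                       length_s = 32) {
  if (peak_delay_s <= 0 || undershoot_delay_s <= 0 || length_s <= 0)
    stop("HRF delays and length must be positive")
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 ratio = ratio, length_s = length_s), class = "hrf_params")
}

#' Sample the double-gamma HRF kernel
#'
#' Difference of two gamma densities (dispersion 1 s each), peak-normalized.
#'
#' @param hrf An [hrf_params()] object.
#' @param dt Sampling interval (s).
#' @return Numeric kernel sampled at \code{0, dt, 2*dt, ...} up to
#'   \code{length_s}.
#' @export
hrf_kernel <- function(hrf = hrf_params(), dt = 0.1) {
  t <- seq(0, hrf$length_s, by = dt)
  h <- stats::dgamma(t, shape = hrf$peak_delay_s, rate = 1) -
    stats::dgamma(t, shape = hrf$undershoot_delay_s, rate = 1) / hrf$ratio
  h / max(h)
}

#' Convolve a box-car with the HRF
#'
#' Causal discrete convolution on the box-car's own time grid; output is
#' truncated to the input length.
#'
#' @param boxcar Non-negative numeric series on a regular grid.
#' @param hrf An [hrf_params()] object.
#' @param dt Grid spacing of \code{boxcar} (s).
#' @return Convolved series, same length as \code{boxcar}.
#' @export
hrf_convolve <- function(boxcar, hrf = hrf_params(), dt = 0.1) {
  if (any(boxcar < 0)) stop("box-car must be non-negative")
  k <- hrf_kernel(hrf, dt)
  full <- stats::convolve(boxcar, rev(k), type = "open")
  full[seq_along(boxcar)] * dt
}

# Build one HRF-convolved regressor sampled at the scan times from a set of
# (onset, duration) events.
.event_regressor <- function(onsets, durations, n_scans, tr, hrf, dt = 0.1) {
  if (length(onsets) == 0L) return(rep(0, n_scans))
  t_end <- n_scans * tr
  grid <- seq(0, t_end, by = dt)
  box <- rep(0, length(grid))
  for (i in seq_along(onsets)) {
    idx <- which(grid >= onsets[i] & grid < onsets[i] + durations[i])
    box[idx] <- 1
  }
  conv <- hrf_convolve(box, hrf, dt)
  scan_t <- (seq_len(n_scans) - 1L) * tr
  conv[pmin(length(conv), round(scan_t / dt) + 1L)]
}

#' Discrete-cosine drift basis
#'
#' Orthonormal DCT regressors spanning frequencies below the high-pass
#' cutoff (the constant term is excluded; the design keeps its own
#' intercept).
#'
#' @param n_scans Number of scans.
#' @param tr Repetition time (s).
#' @param cutoff_hz High-pass cutoff (default 1/128 Hz).
#' @return Matrix \code{n_scans x K} (possibly zero columns).
#' @export
dct_basis <- function(n_scans, tr, cutoff_hz = 1 / 128) {
  n_basis <- floor(2 * n_scans * tr * cutoff_hz)
  if (n_basis < 1L) return(matrix(0, n_scans, 0))
  t <- seq_len(n_scans) - 1L
  X <- vapply(seq_len(n_basis), function(k)
    sqrt(2 / n_scans) * cos(pi * k * (2 * t + 1) / (2 * n_scans)),
    numeric(n_scans))
  colnames(X) <- sprintf("dct%02d", seq_len(n_basis))
  X
}

#' Flag outlier scans from motion and global signal
#'
#' A scan is flagged when its framewise displacement exceeds
#' \code{fd_thresh} (0.9 mm) or its global-signal z-score exceeds
#' \code{z_thresh} (5 SD) in absolute value. FD is the sum of absolute
#' backward differences of the six realignment parameters with rotations
#' converted to arc length on a 50-mm sphere.
#'
#' @param motion \code{n x 6} matrix: translations (mm) then rotations
#'   (radians).
#' @param global_signal Length-n global BOLD series.
#' @param fd_thresh FD threshold (mm).
#' @param z_thresh Global-signal z threshold (SD).
#' @param rotation_radius_mm Sphere radius for rotation conversion (mm).
#' @return Logical vector of length n.
#' @export
flag_outlier_scans <- function(motion, global_signal, fd_thresh = 0.9,
                               z_thresh = 5, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) != length(global_signal))
    stop("motion and global_signal lengths differ")
  d <- rbind(0, abs(diff(motion)))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  sdg <- stats::sd(global_signal)
  z <- if (is.na(sdg) || sdg == 0) rep(0, length(global_signal))
       else (global_signal - mean(global_signal)) / sdg
  fd > fd_thresh | abs(z) > z_thresh
}

#' Framewise displacement series
#' @inheritParams flag_outlier_scans
#' @return Numeric FD per scan (mm); first scan is 0.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  d <- rbind(0, abs(diff(motion)))
  rowSums(d[, 1:3, drop = FALSE]) +
    rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' Build a first-level design matrix
#'
#' Two variants of the first-level GLM. \code{univariate}: one HRF-convolved
#' box-car per context over its non-outlier erasing trials, plus pooled
#' preparation, score and termination regressors. \code{mvpa}: per block,
#' one regressor per erasing direction (trials 2..17, non-outlier), a null
#' regressor for the block's first trial, and per-block preparation, score
#' and termination regressors. Both variants add one regressor per outlier
#' trial, six motion parameters and their backward-difference gradients, one
#' spike regressor per flagged scan, DCT drift columns below the 1/128 Hz
#' cutoff, and an intercept.
#'
#' @param session A \code{session_design}.
#' @param trials Trial-record data frame carrying \code{outlier} flags
#'   (NULL: no outlier trials).
#' @param variant \code{"univariate"} or \code{"mvpa"}.
#' @param nuisance Optional data frame with motion columns
#'   \code{mot1..mot6} and \code{global_signal}.
#' @param hrf An [hrf_params()] object.
#' @param n_scans Number of scans (default covers the session).
#' @param tr Repetition time (s).
#' @param highpass_hz Drift cutoff (Hz).
#' @return Design matrix with named columns and attribute
#'   \code{column_class} (task, null_first_trial, preparation, score,
#'   termination, outlier_trial, motion, motion_gradient, spike, drift,
#'   intercept).
#' @export
build_design_matrix <- function(session, trials = NULL,
                                variant = c("mvpa", "univariate"),
                                nuisance = NULL, hrf = hrf_params(),
                                n_scans = n_scans_for_session(session),
                                tr = session$timing$tr_s,
                                highpass_hz = 1 / 128) {
  variant <- match.arg(variant)
  ev <- session$events
  if (max(ev$onset + ev$duration) > n_scans * tr)
    stop("events extend beyond the scan window")
  tev <- ev[ev$trial_type == "trial", ]
  key <- paste(tev$block, tev$trial)
  out_flag <- rep(FALSE, nrow(tev))
  if (!is.null(trials)) {
    m <- match(key, paste(trials$block, trials$trial))
    out_flag[!is.na(m)] <- trials$outlier[m[!is.na(m)]]
  }
  cols <- list(); classes <- character(0)
  add <- function(x, name, cls) {
    cols[[length(cols) + 1L]] <<- x
    names(cols)[length(cols)] <<- name
    classes[length(cols)] <<- cls
  }
  reg <- function(sel_ev) .event_regressor(sel_ev$onset, sel_ev$duration,
                                           n_scans, tr, hrf)
  if (variant == "univariate") {
    for (cx in context_names()) {
      sel <- tev$context == cx & !out_flag
      if (!any(sel)) stop("no usable erasing trials for context ", cx)
      add(reg(tev[sel, ]), paste0("erase_", cx), "task")
    }
    for (ty in c("preparation", "score", "termination"))
      add(reg(ev[ev$trial_type == ty, ]), ty, ty)
  } else {
    for (blk in session$blocks) {
      b <- blk$block_index
      bsel <- tev$block == b
      if (all(out_flag[bsel])) stop("all trials of block ", b, " are outliers")
      for (dr in direction_labels()$name) {
        sel <- bsel & tev$visual_direction == dr & tev$trial > 1L & !out_flag
        if (any(sel)) add(reg(tev[sel, ]), sprintf("b%02d_%s", b, dr), "task")
      }
      first_sel <- bsel & tev$trial == 1L & !out_flag
      if (any(first_sel))
        add(reg(tev[first_sel, ]), sprintf("b%02d_null", b), "null_first_trial")
      for (ty in c("preparation", "score", "termination")) {
        sel_ev <- ev[ev$trial_type == ty & ev$block == b, ]
        add(reg(sel_ev), sprintf("b%02d_%s", b, substr(ty, 1, 4)), ty)
      }
    }
  }
  if (any(out_flag)) {
    outl <- tev[out_flag, ]
    for (i in seq_len(nrow(outl)))
      add(reg(outl[i, ]),
          sprintf("outlier_b%02d_t%02d", outl$block[i], outl$trial[i]),
          "outlier_trial")
  }
  if (!is.null(nuisance)) {
    mot <- as.matrix(nuisance[, sprintf("mot%d", 1:6)])
    if (nrow(mot) != n_scans) stop("nuisance table length != n_scans")
    for (j in 1:6) add(mot[, j], sprintf("mot%d", j), "motion")
    grad <- rbind(0, diff(mot))
    for (j in 1:6) add(grad[, j], sprintf("dmot%d", j), "motion_gradient")
    if ("global_signal" %in% names(nuisance)) {
      spikes <- which(flag_outlier_scans(mot, nuisance$global_signal))
      for (s in spikes) {
        v <- rep(0, n_scans); v[s] <- 1
        add(v, sprintf("spike_%04d", s), "spike")
      }
    }
  }
  drift <- dct_basis(n_scans, tr, highpass_hz)
  for (j in seq_len(ncol(drift))) add(drift[, j], colnames(drift)[j], "drift")
  add(rep(1, n_scans), "constant", "intercept")
  X <- do.call(cbind, cols)
  attr(X, "column_class") <- stats::setNames(classes, colnames(X))
  X
}

#' Fit a voxelwise ordinary least squares GLM
#'
#' @param Y \code{n_scans x n_voxels} data matrix.
#' @param X Design matrix from [build_design_matrix()] (or any numeric
#'   matrix with named columns).
#' @return List of class \code{glm_fit}: \code{betas}
#'   (\code{n_regressors x n_voxels}), \code{sigma2} (residual variance per
#'   voxel), \code{df}, and the design's column classes.
#' @export
fit_glm <- function(Y, X) {
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("Y and X row counts differ")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  betas <- qr.coef(qrx, Y)
  resid <- Y - X %*% betas
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  rownames(betas) <- colnames(X)
  structure(list(betas = betas, sigma2 = sigma2, df = df,
                 column_class = attr(X, "column_class")),
            class = "glm_fit")
}

#' Gaussian-smooth a volume
#'
#' Separable 3-D Gaussian smoothing with
#' \code{sigma = fwhm / (2 sqrt(2 log 2))} per axis, in voxel units, with
#' zero padding outside the grid. \code{fwhm_mm = 0} is the identity.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm Full width at half maximum (mm).
#' @param voxel_size_mm Isotropic voxel size (mm).
#' @return Smoothed array of the same dimensions.
#' @export
smooth_volume <- function(volume, fwhm_mm, voxel_size_mm = 3) {
  if (fwhm_mm < 0) stop("fwhm must be >= 0")
  if (fwhm_mm == 0) return(volume)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  out <- volume
  for (axis in 1:3) {
    acc <- array(0, dim(out))
    d <- dim(out)[axis]
    for (j in seq(-r, r)) {
      src <- seq_len(d) - j
      valid <- src >= 1L & src <= d
      idx_to <- which(valid); idx_from <- src[valid]
      if (axis == 1) acc[idx_to, , ] <- acc[idx_to, , ] + k[j + r + 1] * out[idx_from, , ]
      if (axis == 2) acc[, idx_to, ] <- acc[, idx_to, ] + k[j + r + 1] * out[, idx_from, ]
      if (axis == 3) acc[, , idx_to] <- acc[, , idx_to] + k[j + r + 1] * out[, , idx_from]
    }
    out <- acc
  }
  out
}

#' Dump a design matrix to a tab-separated table
#' @param X Design matrix.
#' @param path File path.
#' @export
write_design_matrix <- function(X, path) {
  df <- data.frame(scan = seq_len(nrow(X)), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
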