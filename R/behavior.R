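#' Erasing-task geometry
#'
#' Screen geometry of the line-erasing task: seven 16-pixel square dots form
#' a 112-px line; a trial whose cursor path exceeds one-and-a-half line
#' lengths (1.5 x 7 x 16 = 168 px) counts as an outlier.
#'
#' @param n_dots Number of dots in the line.
#' @param dot_size_px Side of each square dot (px).
#' @param cursor_diameter_px Cursor diameter (px).
#' @return List of class \code{erasing_geometry}, including the derived
#'   \code{line_length_px} and \code{outlier_path_px}.
#' @export
erasing_geometry <- function(n_dots = 7, dot_size_px = 16,
                             cursor_diameter_px = 12) {
  structure(list(
    n_dots = as.integer(n_dots),
    dot_size_px = dot_size_px,
    cursor_diameter_px = cursor_diameter_px,
    line_length_px = n_dots * dot_size_px,
    outlier_path_px = 1.5 * n_dots * dot_size_px
  ), class = "erasing_geometry")
}

#' Hand-movement policies for the trial simulator
#'
#' A mover policy is a function \code{(context, visual_direction, n_steps,
#' dt)} returning an \code{n_steps x 2} matrix of per-step hand
#' displacements (px). The provided constructors work in the cursor frame —
#' progress along the required visual direction plus optional perpendicular
#' wiggle — and convert to hand displacements through the inverse context
#' transform, so the cursor follows the line while the hand moves in the
#' context-appropriate direction.
#'
#' \code{mover_zero} never moves; \code{mover_ideal} moves straight along the
#' line at constant speed; \code{mover_sine} adds a sinusoidal perpendicular
#' wiggle of amplitude \code{amp_px} (kept under half a dot so no dot is
#' missed) and frequency \code{freq_hz}, lengthening the path without
#' changing progress — large wiggle emulates the exploratory movements that
#' trip the outlier-path rule.
#'
#' @param progress_px_s Along-line cursor speed (px/s).
#' @param amp_px Perpendicular wiggle amplitude (px; < 8 keeps dots hit).
#' @param freq_hz Wiggle frequency (Hz).
#' @param phase Wiggle phase (radians).
#' @return A mover policy function.
#' @export
mover_zero <- function() {
  function(context, visual_direction, n_steps, dt) matrix(0, n_steps, 2)
}

#' @rdname mover_zero
#' @export
mover_ideal <- function(progress_px_s) {
  mover_sine(progress_px_s, amp_px = 0, freq_hz = 0)
}

#' @rdname mover_zero
#' @export
mover_sine <- function(progress_px_s, amp_px = 2, freq_hz = 1, phase = 0) {
  force(progress_px_s); force(amp_px); force(freq_hz); force(phase)
  function(context, visual_direction, n_steps, dt) {
    tt <- seq_len(n_steps) * dt
    along <- progress_px_s * tt
    perp <- amp_px * sin(2 * pi * freq_hz * tt + phase) -
      amp_px * sin(phase)
    u <- direction_vector(visual_direction)
    u_perp <- c(-u[2], u[1])
    cursor <- cbind(along * u[1] + perp * u_perp[1],
                    along * u[2] + perp * u_perp[2])
    steps <- rbind(cursor[1, ], diff(cursor))
    inv <- context_transforms()[[context]]$inverse
    steps %*% t(inv)
  }
}

#' Simulate one erasing trial
#'
#' Runs a mover policy through the context transform and the erasing rules:
#' dots sit along the visual direction at one-dot-size spacing starting one
#' dot size from the cursor start; a dot is erased when the cursor center is
#' strictly inside its square and all earlier dots are gone; the trial ends
#' at full erasure or at the trial window.
#'
#' @param context Context name.
#' @param visual_direction Visual direction label.
#' @param policy Mover policy (see [mover_zero()]).
#' @param geometry An [erasing_geometry()].
#' @param dt Simulation time step (s).
#' @param trial_window_s Maximum trial duration (s).
#' @return One-row data frame: context, visual_direction, movement_direction,
#'   n_erased, duration_s, path_length_px, outlier.
#' @export
simulate_erasing_trial <- function(context, visual_direction, policy,
                                   geometry = erasing_geometry(), dt = 0.02,
                                   trial_window_s = 3.5) {
  n_steps <- as.integer(ceiling(trial_window_s / dt))
  hand <- policy(context, visual_direction, n_steps, dt)
  if (!all(is.finite(hand))) stop("mover policy produced a non-finite path")
  tmat <- context_transforms()[[context]]$matrix
  cursor_steps <- hand %*% t(tmat)
  pos <- apply(cursor_steps, 2, cumsum)
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1)
  u <- direction_vector(visual_direction)
  half <- geometry$dot_size_px / 2
  centers <- geometry$dot_size_px * seq_len(geometry$n_dots)
  times <- seq_len(n_steps) * dt
  erase_time <- rep(NA_real_, geometry$n_dots)
  from <- 1L
  for (k in seq_len(geometry$n_dots)) {
    cx <- centers[k] * u
    inside <- abs(pos[, 1] - cx[1]) < half & abs(pos[, 2] - cx[2]) < half
    hit <- which(inside & seq_len(n_steps) >= from)
    if (length(hit) == 0L) break
    erase_time[k] <- times[hit[1]]
    from <- hit[1]
  }
  n_erased <- sum(!is.na(erase_time))
  duration <- if (n_erased == geometry$n_dots) erase_time[n_erased] else trial_window_s
  last_step <- min(n_steps, as.integer(ceiling(duration / dt)))
  path <- sum(sqrt(rowSums(cursor_steps[seq_len(last_step), , drop = FALSE]^2)))
  data.frame(
    context = context,
    visual_direction = visual_direction,
    movement_direction = required_movement(context, visual_direction),
    n_erased = n_erased,
    duration_s = duration,
    path_length_px = path,
    outlier = detect_outlier_trial(path, geometry),
    stringsAsFactors = FALSE
  )
}

#' Erasing speed of a trial
#'
#' Dots erased per second: \code{n_erased / duration_s}.
#'
#' @param trial One-row trial record (or a data frame of trials).
#' @return Numeric vector of dots/s.
#' @export
erasing_speed <- function(trial) {
  if (any(trial$duration_s <= 0)) stop("trial duration must be positive")
  trial$n_erased / trial$duration_s
}

#' Flag an outlier trial from its cursor path length
#'
#' A trial is an outlier when the cursor travelled strictly further than
#' one-and-a-half line lengths (168 px for the default geometry).
#'
#' @param path_length_px Cursor path length (px).
#' @param geometry An [erasing_geometry()].
#' @return Logical vector.
#' @export
detect_outlier_trial <- function(path_length_px, geometry = erasing_geometry()) {
  if (any(path_length_px < 0)) stop("path length must be non-negative")
  path_length_px > geometry$outlier_path_px
}

#' Simulate a subject's behavior across a session
#'
#' Draws per-trial along-line speeds around context-specific target erasing
#' speeds, runs the trial simulator for every trial of the session, and
#' injects occasional exploratory (high-wiggle) trials that exceed the
#' outlier path threshold.
#'
#' @param session A \code{session_design}.
#' @param target_speed Named numeric: target erasing speed (dots/s) per
#'   context family, names \code{rotation} and \code{mirror}.
#' @param speed_sd Lognormal sd of per-trial progress-speed noise.
#' @param p_outlier Probability a trial is exploratory (outlier wiggle).
#' @param geometry An [erasing_geometry()].
#' @param dt Simulation time step (s).
#' @return Data frame of trial records with block and trial indices.
#' @export
simulate_subject_behavior <- function(session,
                                      target_speed = c(rotation = 1.7, mirror = 2.4),
                                      speed_sd = 0.12, p_outlier = 0.04,
                                      geometry = erasing_geometry(),
                                      dt = 0.02) {
  tw <- session$timing$trial_window_s
  v0 <- c(rotation = progress_speed_for_target(target_speed[["rotation"]],
                                               speed_sd, geometry, tw),
          mirror = progress_speed_for_target(target_speed[["mirror"]],
                                             speed_sd, geometry, tw))
  out <- list()
  for (blk in session$blocks) {
    fam <- if (blk$context == "mirror") "mirror" else "rotation"
    for (i in seq_along(blk$trial_sequence)) {
      v <- v0[[fam]] * exp(stats::rnorm(1, 0, speed_sd))
      expl <- stats::runif(1) < p_outlier
      pol <- if (expl) mover_sine(v, amp_px = 6, freq_hz = 3)
             else mover_sine(v, amp_px = 2, freq_hz = 1)
      tr <- simulate_erasing_trial(blk$context, blk$trial_sequence[i], pol,
                                   geometry, dt, tw)
      tr$block <- blk$block_index
      tr$trial <- i
      out[[length(out) + 1L]] <- tr
    }
  }
  trials <- do.call(rbind, out)
  trials[, c("block", "trial", "context", "visual_direction",
             "movement_direction", "n_erased", "duration_s",
             "path_length_px", "outlier")]
}

# Deterministic erasing speed of a straight mover with progress speed v:
# dot k needs along-progress > k*16 - 8; completed trials end at the last
# erasure, incomplete ones at the full window.
.speed_of_progress <- function(v, geometry, trial_window_s) {
  reach <- v * trial_window_s
  enter <- geometry$dot_size_px * seq_len(geometry$n_dots) -
    geometry$dot_size_px / 2
  n <- sum(reach > enter)
  if (n == geometry$n_dots) geometry$n_dots / (enter[geometry$n_dots] / v)
  else n / trial_window_s
}

# Invert the expected erasing speed under lognormal per-trial speed noise
# to find the base progress speed hitting a target mean erasing speed. The
# monotone forward map is tabulated once per (speed_sd, geometry, window)
# and inverted by interpolation.
.speed_cache <- new.env(parent = emptyenv())

progress_speed_for_target <- function(target, speed_sd = 0.12,
                                      geometry = erasing_geometry(),
                                      trial_window_s = 3.5) {
  key <- paste(speed_sd, geometry$n_dots, geometry$dot_size_px,
               trial_window_s, sep = "|")
  tab <- .speed_cache[[key]]
  if (is.null(tab)) {
    v_grid <- seq(1, 500, by = 0.5)
    z <- seq(-4, 4, length.out = 33)
    wz <- stats::dnorm(z); wz <- wz / sum(wz)
    exp_speed <- vapply(v_grid, function(v0)
      sum(wz * vapply(z, function(zz)
        .speed_of_progress(v0 * exp(speed_sd * zz), geometry,
                           trial_window_s), 0)), 0)
    tab <- list(v = v_grid, s = exp_speed)
    .speed_cache[[key]] <- tab
  }
  if (target < min(tab$s) || target > max(tab$s))
    stop("target erasing speed outside the attainable range")
  stats::approx(tab$s, tab$v, xout = target, ties = mean)$y
}

#' Fast behavioral draw for a session
#'
#' Statistical shortcut around the trial mechanics used when generating
#' large cohorts: per-trial erasing outcomes come from the deterministic
#' straight-mover speed map under the same lognormal speed noise, and path
#' lengths use the mean wiggle factors of the normal and exploratory
#' policies. Matches [simulate_subject_behavior()] in distribution of the
#' performance summaries.
#'
#' @inheritParams simulate_subject_behavior
#' @return Data frame of trial records with block and trial indices.
#' @export
simulate_subject_behavior_fast <- function(session,
                                           target_speed = c(rotation = 1.7, mirror = 2.4),
                                           speed_sd = 0.12, p_outlier = 0.04,
                                           geometry = erasing_geometry()) {
  tw <- session$timing$trial_window_s
  v0 <- c(rotation = progress_speed_for_target(target_speed[["rotation"]],
                                               speed_sd, geometry, tw),
          mirror = progress_speed_for_target(target_speed[["mirror"]],
                                             speed_sd, geometry, tw))
  enter <- geometry$dot_size_px * seq_len(geometry$n_dots) -
    geometry$dot_size_px / 2
  out <- list()
  for (blk in session$blocks) {
    fam <- if (blk$context == "mirror") "mirror" else "rotation"
    nt <- length(blk$trial_sequence)
    v <- v0[[fam]] * exp(stats::rnorm(nt, 0, speed_sd))
    expl <- stats::runif(nt) < p_outlier
    n_er <- pmin(geometry$n_dots, rowSums(outer(v * tw, enter, ">")))
    dur <- ifelse(n_er == geometry$n_dots, enter[geometry$n_dots] / v, tw)
    wig <- ifelse(expl, 2.9, 1.06)
    out[[length(out) + 1L]] <- data.frame(
      block = blk$block_index, trial = seq_len(nt), context = blk$context,
      visual_direction = blk$trial_sequence,
      movement_direction = required_movement(rep(blk$context, nt),
                                             blk$trial_sequence),
      n_erased = n_er, duration_s = dur,
      path_length_px = v * dur * wig,
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, out)
  trials$outlier <- detect_outlier_trial(trials$path_length_px, geometry)
  trials
}

#' Summarize a subject's task performance
#'
#' Context-wise mean erasing speeds, the mean over the two rotation
#' contexts, and the absolute rotation-mirror performance gap used as the
#' behavioral confound in the group analyses.
#'
#' @param trials Trial-record data frame (from
#'   [simulate_subject_behavior()] or a read trial log).
#' @param include_outliers Include outlier trials in the means (default
#'   TRUE; outliers are excluded from GLM regressors, not necessarily from
#'   behavior summaries).
#' @return List of class \code{subject_performance}: \code{per_trial_speed},
#'   \code{mean_speed_by_context}, \code{mean_rotation_speed},
#'   \code{mean_mirror_speed}, \code{abs_rotation_mirror_diff}.
#' @export
summarize_performance <- function(trials, include_outliers = TRUE) {
  keep <- if (include_outliers) rep(TRUE, nrow(trials)) else !trials$outlier
  tr <- trials[keep, ]
  sp <- erasing_speed(tr)
  by_ctx <- vapply(context_names(), function(cx) {
    idx <- tr$context == cx
    if (!any(idx)) stop("no usable trials for context ", cx)
    mean(sp[idx])
  }, 0)
  rot <- mean(by_ctx[c("rot_minus90", "rot_plus90")])
  mir <- by_ctx[["mirror"]]
  structure(list(
    per_trial_speed = sp,
    mean_speed_by_context = by_ctx,
    mean_rotation_speed = rot,
    mean_mirror_speed = mir,
    abs_rotation_mirror_diff = abs(rot - mir)
  ), class = "subject_performance")
}

#' @export
print.subject_performance <- function(x, ...) {
  cat("Erasing speed (dots/s):\n")
  print(round(x$mean_speed_by_context, 3))
  cat("rotation mean:", round(x$mean_rotation_speed, 3),
      " |rotation - mirror|:", round(x$abs_rotation_mirror_diff, 3), "\n")
  invisible(x)
}

#' Write or read a trial log
#'
#' Tab-separated table mirroring the trial-record fields.
#'
#' @param trials Trial-record data frame.
#' @param path File path.
#' @return \code{read_trials} returns the data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  need <- c("block", "trial", "context", "visual_direction",
            "movement_direction", "n_erased", "duration_s", "path_length_px",
            "outlier")
  missing <- setdiff(need, names(tr))
  if (length(missing) > 0)
    stop("trial log at ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  tr
}
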