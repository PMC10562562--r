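#' Analysis names of the conjunctional decoding designs
#' @return Character vector of the four erasing-data analyses.
#' @export
analysis_names <- function() {
  c("visual", "movement", "context_rot_rot", "context_rot_mirror")
}

# One condition cell: a (context, visual direction) pair with its class
# label; movement direction is implied by the context.
.cell <- function(context, visual, class) {
  data.frame(context = context, visual_direction = visual,
             movement_direction = required_movement(context, visual),
             class = class, stringsAsFactors = FALSE)
}

# Direction-matched condition set within one context: the two directions of
# one axis labeled +1 / -1 at the given level.
.axis_set <- function(context, axis, level) {
  if (level == "visual") {
    rbind(.cell(context, axis[1], 1), .cell(context, axis[2], -1))
  } else {
    rbind(.cell(context, visual_of_movement(context, axis[1]), 1),
          .cell(context, visual_of_movement(context, axis[2]), -1))
  }
}

# Context-labeled set matched on one level: for each of the two contexts
# (classes +1 / -1) the cell whose given-level direction equals dir.
.matched_set <- function(contexts, level, dir) {
  vis <- if (level == "visual") c(dir, dir)
         else c(visual_of_movement(contexts[1], dir),
                visual_of_movement(contexts[2], dir))
  rbind(.cell(contexts[1], vis[1], 1), .cell(contexts[2], vis[2], -1))
}

.cells_disjoint <- function(a, b) {
  !any(paste(a$context, a$visual_direction) %in%
         paste(b$context, b$visual_direction))
}

#' Enumerate the train/test set pairs of a decoding analysis
#'
#' Builds the cross-classification train/test condition-set pairs that
#' restrict generalization to a single representation level. For the
#' \code{visual} and \code{movement} analyses, pairs cross two contexts on
#' one direction axis so the other-level directions (and the context)
#' differ between train and test; their printed total counts ordered
#' train/test units (12 each). For the context analyses, training cells are
#' matched on one level (visual or movement) and test cells on the other;
#' their printed totals count unordered set pairs (8 for -90 vs +90, 16 for
#' rotation vs mirror), each evaluated in both directions.
#'
#' @param analysis One of [analysis_names()].
#' @param dedup Override the analysis' own counting convention:
#'   \code{TRUE} collapses ordered duplicates to unordered bidirectional
#'   pairs, \code{FALSE} expands to ordered units. Default \code{NA} keeps
#'   the per-analysis convention above.
#' @return List of pairs; each has \code{analysis}, \code{train},
#'   \code{test} (cell data frames with columns context, visual_direction,
#'   movement_direction, class) and \code{directions} ("one" or "both").
#' @export
enumerate_pairs <- function(analysis = analysis_names(), dedup = NA) {
  analysis <- match.arg(analysis)
  dirs <- direction_labels()$name
  axes <- list(vertical = c("up", "down"), horizontal = c("left", "right"))
  pairs <- list()
  if (analysis %in% c("visual", "movement")) {
    ctx <- context_names()
    cpairs <- utils::combn(ctx, 2, simplify = FALSE)
    for (cp in cpairs) for (ax in axes) {
      a <- .axis_set(cp[1], ax, analysis)
      b <- .axis_set(cp[2], ax, analysis)
      # cross-context: the other-level directions must differ per label
      other <- if (analysis == "visual") "movement_direction" else "visual_direction"
      stopifnot(all(a[[other]] != b[[other]]))
      pairs[[length(pairs) + 1L]] <- list(analysis = analysis, train = a,
                                          test = b, directions = "both")
    }
    unordered_default <- FALSE
  } else {
    cps <- if (analysis == "context_rot_rot")
      list(c("rot_minus90", "rot_plus90"))
    else list(c("rot_minus90", "mirror"), c("rot_plus90", "mirror"))
    for (cp in cps) for (v in dirs) {
      train <- .matched_set(cp, "visual", v)
      for (m in dirs) {
        test <- .matched_set(cp, "movement", m)
        if (.cells_disjoint(train, test))
          pairs[[length(pairs) + 1L]] <- list(analysis = analysis,
                                              train = train, test = test,
                                              directions = "both")
      }
    }
    unordered_default <- TRUE
  }
  if (is.na(dedup)) dedup <- unordered_default
  if (!dedup) {
    ordered <- list()
    for (p in pairs) {
      ordered[[length(ordered) + 1L]] <-
        list(analysis = p$analysis, train = p$train, test = p$test,
             directions = "one")
      ordered[[length(ordered) + 1L]] <-
        list(analysis = p$analysis, train = p$test, test = p$train,
             directions = "one")
    }
    pairs <- ordered
  }
  pairs
}

#' Leave-two-block-out cross-validation folds
#'
#' For analyses whose train and test sets draw on the same context blocks:
#' fold k holds out the k-th repetition block of each of the two classes
#' (two temporally adjacent blocks in repetition order) and trains on the
#' remaining repetitions.
#'
#' @param n_reps Repetitions per context (5 in the standard session).
#' @return List of folds, each with \code{test_rep} and \code{train_reps}.
#' @export
leave_two_block_out_folds <- function(n_reps = 5) {
  if (n_reps < 2) stop("need at least two repetitions per context")
  lapply(seq_len(n_reps), function(k)
    list(test_rep = k, train_reps = setdiff(seq_len(n_reps), k)))
}

#' Searchlight sphere membership
#'
#' For every in-mask voxel, the in-mask voxels whose center lies within
#' \code{radius_mm} (Euclidean center-to-center distance, inclusive).
#'
#' @param grid A [volume_grid()].
#' @param radius_mm Sphere radius (mm).
#' @return Object of class \code{searchlight}: \code{members} (0-padded
#'   integer matrix, one row per in-mask voxel, entries are 1-based in-mask
#'   row indices), \code{counts}, \code{n_offsets} (sphere size away from
#'   edges), \code{vox_index} (1-based linear grid index per row).
#' @export
searchlight_spheres <- function(grid, radius_mm = 9) {
  if (radius_mm < 0) stop("radius must be >= 0")
  d <- grid$dims
  vs <- grid$voxel_size_mm
  r_vox <- floor(radius_mm / vs)
  off <- expand.grid(x = -r_vox:r_vox, y = -r_vox:r_vox, z = -r_vox:r_vox)
  off <- off[sqrt(rowSums(off^2)) * vs <= radius_mm, , drop = FALSE]
  vox_index <- which(grid$mask)
  lookup <- array(0L, d)
  lookup[vox_index] <- seq_along(vox_index)
  coord <- arrayInd(vox_index, d)
  members <- matrix(0L, length(vox_index), nrow(off))
  for (j in seq_len(nrow(off))) {
    nx <- coord[, 1] + off$x[j]
    ny <- coord[, 2] + off$y[j]
    nz <- coord[, 3] + off$z[j]
    ok <- nx >= 1L & nx <= d[1] & ny >= 1L & ny <= d[2] & nz >= 1L & nz <= d[3]
    lin <- (nz - 1L) * d[1] * d[2] + (ny - 1L) * d[1] + nx
    row <- integer(length(vox_index))
    row[ok] <- lookup[lin[ok]]
    members[, j] <- row
  }
  structure(list(members = members, counts = rowSums(members > 0L),
                 n_offsets = nrow(off), vox_index = vox_index,
                 radius_mm = radius_mm),
            class = "searchlight")
}

#' Decoding configuration
#'
#' @param radius_mm Searchlight radius (mm).
#' @param cost Soft-margin cost C of the linear SVM.
#' @param center Per-sphere feature centering by the training mean.
#' @param use_folds Apply leave-two-block-out folds in the context
#'   analyses (\code{FALSE} reproduces the correlation-analysis variant,
#'   which does not subdivide the pairs).
#' @return List of class \code{decoding_config}.
#' @export
decoding_config <- function(radius_mm = 9, cost = 1, center = TRUE,
                            use_folds = TRUE) {
  structure(list(radius_mm = radius_mm, cost = cost, center = center,
                 use_folds = use_folds), class = "decoding_config")
}

#' Train a linear SVM and score a test set
#'
#' Soft-margin linear support vector machine (dual coordinate descent),
#' deterministic given its inputs.
#'
#' @param train_features,test_features Numeric matrices (samples x
#'   features).
#' @param train_labels,test_labels Labels coercible to two classes.
#' @param cost Soft-margin cost C.
#' @param center Center features by the training mean.
#' @return Accuracy in \code{[0, 1]}, with attribute \code{decision}.
#' @export
classify <- function(train_features, train_labels, test_features,
                     test_labels, cost = 1, center = FALSE) {
  train_features <- as.matrix(train_features)
  test_features <- as.matrix(test_features)
  lv <- sort(unique(train_labels))
  if (length(lv) != 2L) stop("training set must contain exactly two classes")
  ytr <- ifelse(train_labels == lv[2], 1, -1)
  yte <- ifelse(test_labels == lv[2], 1, -1)
  if (center) {
    mu <- colMeans(train_features)
    train_features <- sweep(train_features, 2, mu)
    test_features <- sweep(test_features, 2, mu)
  }
  fit <- cpp_svm_train(train_features, ytr, cost)
  dec <- as.numeric(cpp_svm_decision(test_features, fit$w, fit$b))
  acc <- mean(ifelse(dec >= 0, 1, -1) == yte)
  attr(acc, "decision") <- dec
  acc
}

# Sample selector: rows of the beta-series info matching one cell at given
# repetitions.
.cell_samples <- function(info, cell, reps) {
  which(info$regressor %in% direction_labels()$name &
          info$context == cell$context &
          info$visual_direction == cell$visual_direction &
          info$rep %in% reps)
}

# Expand pairs (and folds) into classifier jobs over beta-series samples.
.decoding_jobs <- function(info, pairs, use_folds, n_reps = 5) {
  all_reps <- seq_len(n_reps)
  folds <- if (use_folds) leave_two_block_out_folds(n_reps)
           else list(list(test_rep = all_reps, train_reps = all_reps))
  jobs <- list()
  add_job <- function(train_cells, test_cells, train_reps, test_reps) {
    tr <- list(); ty <- list(); te <- list(); tey <- list()
    for (i in seq_len(nrow(train_cells))) {
      s <- .cell_samples(info, train_cells[i, ], train_reps)
      tr[[i]] <- s; ty[[i]] <- rep(train_cells$class[i], length(s))
    }
    for (i in seq_len(nrow(test_cells))) {
      s <- .cell_samples(info, test_cells[i, ], test_reps)
      te[[i]] <- s; tey[[i]] <- rep(test_cells$class[i], length(s))
    }
    train <- unlist(tr); test <- unlist(te)
    if (length(train) == 0L || length(test) == 0L)
      stop("missing condition cells in the beta series")
    jobs[[length(jobs) + 1L]] <<- list(train = train, train_y = unlist(ty),
                                       test = test, test_y = unlist(tey))
  }
  for (p in pairs) {
    same_blocks <- any(p$train$context %in% p$test$context)
    for (f in (if (same_blocks) folds else list(list(test_rep = all_reps,
                                                     train_reps = all_reps)))) {
      add_job(p$train, p$test, f$train_reps, f$test_rep)
      if (identical(p$directions, "both"))
        add_job(p$test, p$train, f$train_reps, f$test_rep)
    }
  }
  jobs
}

#' Accuracy-minus-chance map container
#' @param grid A [volume_grid()].
#' @param values In-mask accuracy-minus-chance values (percentage points).
#' @param analysis Analysis tag.
#' @param subject_id Subject identifier.
#' @param n_tests Total test classifications behind each voxel's value.
#' @return Object of class \code{accuracy_map}.
#' @export
accuracy_map <- function(grid, values, analysis, subject_id = NA,
                         n_tests = NA) {
  structure(list(grid = grid, values = values, analysis = analysis,
                 subject_id = subject_id, n_tests = n_tests),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  cat("Accuracy-minus-chance map (", x$analysis, ", ",
      as.character(x$subject_id), "): mean ",
      round(mean(x$values, na.rm = TRUE), 2), " pp, max ",
      round(max(x$values, na.rm = TRUE), 2), " pp\n", sep = "")
  invisible(x)
}

#' Run a searchlight cross-decoding analysis for one subject
#'
#' Per searchlight sphere, trains and tests the linear SVM over all
#' train/test set pairs of the analysis (both directions for unordered
#' pairs, leave-two-block-out folds where the analysis uses them), averages
#' the accuracies and subtracts the 50% chance level.
#'
#' @param subject A \code{subject_dataset}.
#' @param analysis One of [analysis_names()].
#' @param config A [decoding_config()].
#' @param spheres Optional precomputed [searchlight_spheres()] (reused
#'   across subjects and analyses).
#' @param roi_mask Optional logical array restricting the searchlight
#'   centers (values elsewhere are NA).
#' @return An [accuracy_map()] in percentage points, bounded in
#'   \code{[-50, 50]}.
#' @export
run_searchlight_decoding <- function(subject, analysis,
                                     config = decoding_config(),
                                     spheres = NULL, roi_mask = NULL) {
  analysis <- match.arg(analysis, analysis_names())
  betas <- subject$betas
  grid <- betas$grid
  if (is.null(spheres)) spheres <- searchlight_spheres(grid, config$radius_mm)
  pairs <- enumerate_pairs(analysis)
  use_folds <- config$use_folds &&
    analysis %in% c("context_rot_rot", "context_rot_mirror")
  jobs <- .decoding_jobs(betas$info, pairs, use_folds)
  members <- spheres$members
  keep <- rep(TRUE, nrow(members))
  if (!is.null(roi_mask)) keep <- roi_mask[grid$mask]
  acc <- rep(NA_real_, nrow(members))
  acc[keep] <- cpp_searchlight(betas$coefficients,
                               members[keep, , drop = FALSE], jobs,
                               config$cost, config$center)
  n_tests <- sum(vapply(jobs, function(j) length(j$test), 0L))
  accuracy_map(grid, (acc - 0.5) * 100, analysis, subject$subject_id,
               n_tests = n_tests)
}

#' Decode task context from preparation-period betas
#'
#' Uses the per-block preparation betas (five per context) as features.
#' \code{rot_rot}: -90 vs +90 with leave-two-out CV over repetition pairs
#' (5 folds). \code{rot_mirror}: -90-vs-mirror and +90-vs-mirror leave-two-
#' out schemes (5 folds each, 10 in total), averaged; chance is subtracted.
#'
#' @param subject A \code{subject_dataset}.
#' @param contrast \code{"rot_rot"} or \code{"rot_mirror"}.
#' @param config A [decoding_config()].
#' @param spheres Optional precomputed [searchlight_spheres()].
#' @param roi_mask Optional logical array restricting searchlight centers.
#' @return An [accuracy_map()].
#' @export
preparation_decoding <- function(subject, contrast = c("rot_rot", "rot_mirror"),
                                 config = decoding_config(), spheres = NULL,
                                 roi_mask = NULL) {
  contrast <- match.arg(contrast)
  betas <- subject$betas
  info <- betas$info
  grid <- betas$grid
  if (is.null(spheres)) spheres <- searchlight_spheres(grid, config$radius_mm)
  prep_rows <- function(ctx, reps)
    which(info$regressor == "prep" & info$context == ctx & info$rep %in% reps)
  ctx_pairs <- if (contrast == "rot_rot")
    list(c("rot_minus90", "rot_plus90"))
  else list(c("rot_minus90", "mirror"), c("rot_plus90", "mirror"))
  jobs <- list()
  for (cp in ctx_pairs) {
    if (length(prep_rows(cp[1], 1:5)) < 5L || length(prep_rows(cp[2], 1:5)) < 5L)
      stop("missing preparation betas for contrast ", contrast)
    for (f in leave_two_block_out_folds(5)) {
      tr1 <- prep_rows(cp[1], f$train_reps); tr2 <- prep_rows(cp[2], f$train_reps)
      te1 <- prep_rows(cp[1], f$test_rep); te2 <- prep_rows(cp[2], f$test_rep)
      jobs[[length(jobs) + 1L]] <- list(
        train = c(tr1, tr2), train_y = c(rep(1, length(tr1)), rep(-1, length(tr2))),
        test = c(te1, te2), test_y = c(rep(1, length(te1)), rep(-1, length(te2))))
    }
  }
  members <- spheres$members
  keep <- rep(TRUE, nrow(members))
  if (!is.null(roi_mask)) keep <- roi_mask[grid$mask]
  acc <- rep(NA_real_, nrow(members))
  acc[keep] <- cpp_searchlight(betas$coefficients,
                               members[keep, , drop = FALSE], jobs,
                               config$cost, config$center)
  accuracy_map(grid, (acc - 0.5) * 100, paste0("prep_", contrast),
               subject$subject_id,
               n_tests = sum(vapply(jobs, function(j) length(j$test), 0L)))
}

#' ROI cross-decoding accuracy
#'
#' Runs the same pair/fold jobs as the searchlight analyses but with a
#' single feature set: all voxels of the ROI. Used for region-level
#' follow-ups and the correlation analyses.
#'
#' @param subject A \code{subject_dataset}.
#' @param roi_mask Logical array over the grid.
#' @param analysis One of [analysis_names()].
#' @param config A [decoding_config()].
#' @return Accuracy minus chance (percentage points), with attribute
#'   \code{n_tests}.
#' @export
roi_decoding <- function(subject, roi_mask, analysis,
                         config = decoding_config()) {
  analysis <- match.arg(analysis, analysis_names())
  betas <- subject$betas
  rows <- which(roi_mask[betas$grid$mask])
  if (length(rows) == 0L) stop("ROI mask is empty")
  pairs <- enumerate_pairs(analysis)
  use_folds <- config$use_folds &&
    analysis %in% c("context_rot_rot", "context_rot_mirror")
  jobs <- .decoding_jobs(betas$info, pairs, use_folds)
  members <- matrix(rows, nrow = 1)
  acc <- cpp_searchlight(betas$coefficients, members, jobs, config$cost,
                         config$center)
  out <- (acc[1] - 0.5) * 100
  attr(out, "n_tests") <- sum(vapply(jobs, function(j) length(j$test), 0L))
  out
}

#' Export a pair enumeration as an audit table
#'
#' @param analysis One of [analysis_names()].
#' @param path Optional file path for a tab-separated dump.
#' @return Data frame: pair, role, context, visual_direction,
#'   movement_direction, class.
#' @export
pair_audit_table <- function(analysis, path = NULL) {
  pairs <- enumerate_pairs(analysis)
  rows <- list()
  for (i in seq_along(pairs)) {
    for (role in c("train", "test")) {
      cells <- pairs[[i]][[role]]
      cells$pair <- i; cells$role <- role; cells$analysis <- analysis
      rows[[length(rows) + 1L]] <- cells
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("analysis", "pair", "role", "context", "visual_direction",
                 "movement_direction", "class")]
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
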