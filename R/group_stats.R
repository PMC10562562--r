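#' Group-level design
#'
#' One row per subject: an intercept, optionally a covariate of interest
#' and/or a behavioral confound. Following the construction used for the
#' confounded one-sample tests, the confound is entered without centering
#' and the test targets the intercept; covariate tests target the covariate
#' column. All tests are one-sided.
#'
#' @param n_subjects Number of subjects.
#' @param covariate Optional numeric covariate (e.g. performance).
#' @param confound Optional numeric confound (e.g. the absolute
#'   rotation-mirror performance gap), entered uncentered.
#' @param tested \code{"intercept"} or \code{"covariate"}.
#' @param alternative \code{"greater"} (default) or \code{"less"}; the
#'   one-sided direction of the test.
#' @return Object of class \code{group_design}: \code{X}, \code{test_col},
#'   \code{alternative}.
#' @export
group_design <- function(n_subjects, covariate = NULL, confound = NULL,
                         tested = c("intercept", "covariate"),
                         alternative = c("greater", "less")) {
  tested <- match.arg(tested)
  alternative <- match.arg(alternative)
  X <- cbind(intercept = rep(1, n_subjects))
  if (!is.null(covariate)) {
    if (length(covariate) != n_subjects) stop("covariate length mismatch")
    X <- cbind(X, covariate = covariate)
  }
  if (!is.null(confound)) {
    if (length(confound) != n_subjects) stop("confound length mismatch")
    X <- cbind(X, confound = confound)
  }
  if (tested == "covariate" && is.null(covariate))
    stop("no covariate to test")
  if (qr(X)$rank < ncol(X)) stop("group design is rank deficient")
  structure(list(X = X, test_col = match(tested, colnames(X)),
                 tested = tested, alternative = alternative),
            class = "group_design")
}

#' Voxelwise group GLM t statistics
#'
#' Ordinary least squares t statistic of the tested regressor at every
#' voxel; reduces to the one-sample t when the design is intercept-only.
#' For \code{alternative = "less"} the sign is flipped so that large
#' statistics always support the tested direction.
#'
#' @param maps \code{n_subjects x n_voxels} matrix of subject maps.
#' @param design A [group_design()].
#' @return Numeric vector of t values (one per voxel). Voxels with zero
#'   residual variance get +/-Inf by the usual convention (sign of the
#'   effect), or 0 when the effect is also zero.
#' @export
group_glm_t <- function(maps, design) {
  maps <- as.matrix(maps)
  X <- design$X
  n <- nrow(X); k <- ncol(X)
  if (nrow(maps) != n) stop("maps row count != design rows")
  if (n - k < 1) stop("need at least ", k + 1, " subjects")
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, maps)
  res <- maps - X %*% B
  s2 <- colSums(res^2) / (n - k)
  g <- XtXi[design$test_col, design$test_col]
  eff <- B[design$test_col, ]
  t <- ifelse(s2 > 0, eff / sqrt(s2 * g),
              ifelse(eff == 0, 0, sign(eff) * Inf))
  if (design$alternative == "less") t <- -t
  t
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster support across thresholds:
#' \code{tfce(v) = sum_h e_v(h)^E h^H dh} over heights \code{h} from
#' \code{dh} up to the voxel's statistic, where \code{e_v(h)} is the extent
#' of the 26-connected suprathreshold cluster containing \code{v}. Only the
#' positive branch is enhanced (one-sided use).
#'
#' @param stat 3-D statistic array, or in-mask vector (then \code{grid} is
#'   required).
#' @param grid A [volume_grid()] (required for vector input).
#' @param E,H TFCE exponents (published defaults 0.5 and 2).
#' @param n_steps Number of integration steps when \code{dh} is NULL
#'   (\code{dh = max/n_steps}).
#' @param dh Explicit step height (overrides \code{n_steps}).
#' @return Same shape as \code{stat}.
#' @export
tfce <- function(stat, grid = NULL, E = 0.5, H = 2, n_steps = 100, dh = NULL) {
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  as_array <- is.array(stat) && length(dim(stat)) == 3L
  if (as_array) {
    dims <- dim(stat)
    vox_index <- seq_along(stat)
    vals <- as.numeric(stat)
  } else {
    if (is.null(grid)) stop("grid is required for in-mask vector input")
    dims <- grid$dims
    vox_index <- which(grid$mask)
    vals <- stat
  }
  if (!all(is.finite(vals))) stop("statistic volume must be finite")
  out <- cpp_tfce(vals, vox_index, as.integer(dims), E, H,
                  as.integer(n_steps), if (is.null(dh)) -1 else dh)
  if (as_array) array(out, dims) else as.numeric(out)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment over the in-mask voxels.
#'
#' @param p Vector of p-values in \code{[0, 1]}.
#' @return q-values, same length.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Max-statistic permutation FWE inference
#'
#' Permutation test of the tested regressor with family-wise error control
#' by the maximum statistic: sign-flipping of reduced-model residuals for
#' intercept tests, Freedman-Lane residual permutation for covariate tests.
#' \code{p_fwe(v) = (1 + #\{perm max >= observed(v)\}) / (1 + n_perm)};
#' voxelwise uncorrected permutation p-values feed the FDR q-values.
#'
#' @param maps \code{n_subjects x n_voxels} matrix (in-mask columns).
#' @param design A [group_design()].
#' @param grid A [volume_grid()] matching the map columns.
#' @param statistic \code{"tfce_t"} (TFCE-enhanced t) or \code{"t"}.
#' @param n_perm Number of permutations (the study standard is 5000).
#' @param scheme \code{"auto"}, \code{"sign_flip"} or
#'   \code{"freedman_lane"}.
#' @param E,H,n_steps TFCE parameters (\code{dh = max/n_steps} per map).
#' @return Object of class \code{group_stat_map}: \code{t}, \code{stat}
#'   (enhanced statistic), \code{p_fwe}, \code{q_fdr}, \code{max_dist},
#'   \code{n_perm}, the design and grid.
#' @export
permutation_fwe <- function(maps, design, grid,
                            statistic = c("tfce_t", "t"), n_perm = 5000,
                            scheme = c("auto", "sign_flip", "freedman_lane"),
                            E = 0.5, H = 2, n_steps = 100) {
  statistic <- match.arg(statistic)
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be >= 1")
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (scheme == "auto")
    scheme <- if (design$tested == "intercept") "sign_flip" else "freedman_lane"
  if (scheme == "sign_flip" && design$tested == "covariate")
    stop("sign-flipping is not a valid scheme for covariate tests")
  X <- design$X
  if (design$alternative == "less") {
    X[, design$test_col] <- -X[, design$test_col]
  }
  perm <- if (scheme == "sign_flip") {
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  } else {
    t(replicate(n_perm, sample.int(n)))
  }
  res <- cpp_perm_maxstat(maps, X, design$test_col - 1L, perm,
                          if (scheme == "sign_flip") 0L else 1L,
                          statistic == "tfce_t", which(grid$mask),
                          as.integer(grid$dims), E, H, as.integer(n_steps))
  # the engine keeps only the max-statistic null, so weak (FDR) control
  # runs on parametric one-sided t p-values voxelwise
  p_vox <- stats::pt(res$t, df = n - ncol(X), lower.tail = FALSE)
  structure(list(t = as.numeric(res$t), stat = as.numeric(res$stat),
                 p_fwe = as.numeric(res$p_fwe), q_fdr = fdr_bh(p_vox),
                 p_unc = p_vox, max_dist = as.numeric(res$max_dist),
                 n_perm = n_perm, scheme = scheme, statistic = statistic,
                 design = design, grid = grid),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat("Group statistic map (", x$statistic, ", ", x$scheme, ", ",
      x$n_perm, " permutations)\n", sep = "")
  cat("tested:", x$design$tested, "(one-sided,", x$design$alternative, ")\n")
  cat("voxels:", length(x$t), "; significant at p_FWE < 0.05:",
      sum(x$p_fwe < 0.05), "; at FDR < 0.05:", sum(x$q_fdr < 0.05), "\n")
  invisible(x)
}

#' Accuracy-performance correlation analysis
#'
#' Voxelwise regression of context-decoding accuracy maps on a behavioral
#' performance measure (one value per subject), with an optional uncentered
#' confound; the performance slope is tested one-sided in the negative
#' direction by default (higher performance, lower context-decoding
#' accuracy: the representation-commonality hypothesis).
#'
#' @param maps \code{n_subjects x n_voxels} accuracy-minus-chance maps.
#' @param performance Numeric vector, one value per subject.
#' @param grid A [volume_grid()].
#' @param confound Optional confound vector (uncentered).
#' @param alternative Tested direction of the slope (default "less").
#' @param n_perm Number of permutations.
#' @param statistic See [permutation_fwe()].
#' @return A \code{group_stat_map} for the performance slope.
#' @export
accuracy_performance_correlation <- function(maps, performance, grid,
                                             confound = NULL,
                                             alternative = "less",
                                             n_perm = 5000,
                                             statistic = "tfce_t") {
  if (nrow(as.matrix(maps)) != length(performance))
    stop("one performance value per subject is required")
  design <- group_design(length(performance), covariate = performance,
                         confound = confound, tested = "covariate",
                         alternative = alternative)
  permutation_fwe(maps, design, grid, statistic = statistic, n_perm = n_perm)
}

#' ROI test of subject maps
#'
#' Averages each subject's map over the ROI and runs the specified group
#' GLM test on the resulting scalars (parametric one-sided p).
#'
#' @param maps \code{n_subjects x n_voxels} matrix (in-mask columns).
#' @param roi_mask Logical array over the grid, or logical/index vector
#'   over the in-mask columns.
#' @param design A [group_design()].
#' @param grid A [volume_grid()] (needed for array masks).
#' @return List: \code{t}, \code{p}, \code{df}, \code{roi_mean} (per
#'   subject).
#' @export
roi_test <- function(maps, roi_mask, design, grid = NULL) {
  maps <- as.matrix(maps)
  cols <- if (is.array(roi_mask)) {
    if (is.null(grid)) stop("grid required for an array ROI mask")
    which(roi_mask[grid$mask])
  } else if (is.logical(roi_mask)) which(roi_mask) else roi_mask
  if (length(cols) == 0L) stop("ROI mask is empty")
  m <- rowMeans(maps[, cols, drop = FALSE])
  t <- group_glm_t(matrix(m, ncol = 1), design)
  df <- nrow(design$X) - ncol(design$X)
  list(t = as.numeric(t), p = stats::pt(t, df, lower.tail = FALSE), df = df,
       roi_mean = m)
}

#' Cluster-peak results table
#'
#' 26-connected clusters of voxels significant at the given FWE threshold,
#' with peak statistic, size and the peak's p/q values.
#'
#' @param gsm A \code{group_stat_map}.
#' @param alpha FWE threshold.
#' @param path Optional tab-separated output path.
#' @return Data frame: cluster, size, peak t/stat/p_fwe/q_fdr and peak
#'   voxel coordinates.
#' @export
results_table <- function(gsm, alpha = 0.05, path = NULL) {
  sig <- which(gsm$p_fwe < alpha)
  vox_index <- which(gsm$grid$mask)
  out <- data.frame(cluster = integer(0), size = integer(0),
                    peak_t = numeric(0), peak_stat = numeric(0),
                    peak_p_fwe = numeric(0), peak_q_fdr = numeric(0),
                    x = integer(0), y = integer(0), z = integer(0))
  if (length(sig) > 0) {
    coords <- arrayInd(vox_index[sig], gsm$grid$dims)
    key <- split(seq_along(sig), .label_components(coords))
    rows <- lapply(seq_along(key), function(ci) {
      idx <- sig[key[[ci]]]
      pk <- idx[which.max(gsm$stat[idx])]
      pc <- arrayInd(vox_index[pk], gsm$grid$dims)
      data.frame(cluster = ci, size = length(idx), peak_t = gsm$t[pk],
                 peak_stat = gsm$stat[pk], peak_p_fwe = gsm$p_fwe[pk],
                 peak_q_fdr = gsm$q_fdr[pk], x = pc[1], y = pc[2], z = pc[3])
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$size), ]
    out$cluster <- seq_len(nrow(out))
  }
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

# 26-connectivity component labels for a small set of voxel coordinates.
.label_components <- function(coords) {
  n <- nrow(coords)
  labels <- seq_len(n)
  find <- function(i) { while (labels[i] != i) i <- labels[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j >= i) break
    if (all(abs(coords[i, ] - coords[j, ]) <= 1)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) labels[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, 0L)
}
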