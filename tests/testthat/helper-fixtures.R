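# Small shared fixtures built in code at test time.

# A tiny grid with four disjoint, well-separated 2x2x2 signal regions, for
# fast cohorts (pair a 3-mm searchlight with it when localization matters).
tiny_model <- function(dims = c(12, 12, 8), amplitude = c(visual = 0.35,
                                                          movement = 0.35,
                                                          context = 0.35,
                                                          prep = 0.35),
                       noise_sd = 1, link = link_constant(0.4)) {
  grid <- volume_grid(dims)
  r0 <- array(FALSE, dims)
  a <- max(2L, round(dims[1] * 0.25))
  b <- min(dims[1] - 2L, max(a + 2L, round(dims[1] * 0.7)))
  zc <- max(2L, round(dims[3] / 2) - 1L)
  mk <- function(x, y) {
    m <- r0; m[x + 0:1, y + 0:1, zc + 0:1] <- TRUE; m & grid$mask
  }
  regions <- list(visual_region = mk(a, a),
                  movement_region = mk(b, a),
                  context_region = mk(a, b),
                  null_region = mk(b, b))
  pattern_model(grid, regions, amplitude = amplitude, noise_sd = noise_sd,
                link = link)
}

# Short session (3 blocks, one repetition per context) for GLM tests.
short_timing <- function() timing_params(n_blocks = 3, n_context_reps = 1)

# Independent brute-force TFCE oracle: explicit threshold loop with its own
# 26-connectivity component labeling.
tfce_oracle <- function(vol, E = 0.5, H = 2, dh = NULL, n_steps = 100) {
  stopifnot(is.array(vol))
  hmax <- max(vol)
  out <- array(0, dim(vol))
  if (hmax <= 0) return(out)
  if (is.null(dh)) dh <- hmax / n_steps
  coords_all <- arrayInd(seq_along(vol), dim(vol))
  hs <- seq(dh, hmax + 1e-12, by = dh)
  hs <- hs[hs <= hmax + 1e-12]
  for (h in hs) {
    idx <- which(vol >= h)
    if (length(idx) == 0) next
    coords <- coords_all[idx, , drop = FALSE]
    lab <- seq_along(idx)
    repeat {
      changed <- FALSE
      for (i in seq_along(idx)) for (j in seq_along(idx)) {
        if (i == j) next
        if (all(abs(coords[i, ] - coords[j, ]) <= 1) &&
            lab[j] < lab[i]) {
          lab[i] <- lab[j]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    sizes <- table(lab)
    ext <- as.numeric(sizes[as.character(lab)])
    out[idx] <- out[idx] + ext^E * h^H * dh
  }
  out
}

# Normal-equations GLM t oracle for one tested column.
glm_t_oracle <- function(y, design, col) {
  XtXi <- solve(t(design) %*% design)
  b <- XtXi %*% t(design) %*% y
  res <- y - design %*% b
  s2 <- sum(res^2) / (length(y) - ncol(design))
  b[col] / sqrt(s2 * XtXi[col, col])
}
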