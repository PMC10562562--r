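test_that("HRF convolution is causal and linear", {
  expect_equal(hrf_convolve(rep(0, 100)), rep(0, 100))
  # a unit impulse returns the kernel itself (scaled by dt)
  imp <- c(1, rep(0, 400))
  k <- hrf_kernel(dt = 0.1)
  out <- hrf_convolve(imp, dt = 0.1)
  expect_equal(out[seq_along(k)], k * 0.1)
  # two far-apart impulses superpose
  imp2 <- rep(0, 900); imp2[c(1, 500)] <- 1
  out2 <- hrf_convolve(imp2, dt = 0.1)
  one1 <- rep(0, 900); one1[1] <- 1
  one2 <- rep(0, 900); one2[500] <- 1
  expect_equal(out2, hrf_convolve(one1, dt = 0.1) + hrf_convolve(one2, dt = 0.1))
  expect_error(hrf_convolve(c(-1, 0)), "non-negative")
})

test_that("drift basis is orthonormal below the 1/128 Hz cutoff", {
  D <- dct_basis(200, 2.3)
  expect_equal(ncol(D), floor(2 * 200 * 2.3 / 128))
  expect_equal(unname(crossprod(D)), diag(ncol(D)), tolerance = 1e-10)
  # adding drift columns never increases the residual sum of squares
  set.seed(1)
  y <- rnorm(200)
  X0 <- cbind(1, rnorm(200))
  r0 <- sum(qr.resid(qr(X0), y)^2)
  r1 <- sum(qr.resid(qr(cbind(X0, D)), y)^2)
  expect_lte(r1, r0 + 1e-12)
})

test_that("design matrices follow the two GLM variants", {
  s <- build_session(seed = 42)
  X <- build_design_matrix(s, variant = "mvpa")
  cls <- attr(X, "column_class")
  expect_equal(sum(cls == "task"), 15 * 4)
  expect_equal(sum(cls == "null_first_trial"), 15)
  expect_equal(sum(cls == "preparation"), 15)
  expect_equal(sum(cls == "score"), 15)
  expect_equal(sum(cls == "termination"), 15)
  expect_equal(sum(cls == "outlier_trial"), 0)
  Xu <- build_design_matrix(s, variant = "univariate")
  clsu <- attr(Xu, "column_class")
  expect_equal(sum(clsu == "task"), 3)
  expect_true(all(c("erase_rot_minus90", "erase_rot_plus90", "erase_mirror")
                  %in% colnames(Xu)))
  # an outlier trial leaves its direction regressor and gets its own column
  tr <- simulate_subject_behavior_fast(s)
  tr$outlier <- FALSE
  tr$outlier[tr$block == 2 & tr$trial == 5] <- TRUE
  tr$path_length_px[tr$block == 2 & tr$trial == 5] <- 200
  Xo <- build_design_matrix(s, trials = tr, variant = "mvpa")
  clso <- attr(Xo, "column_class")
  expect_equal(sum(clso == "outlier_trial"), 1)
  expect_true("outlier_b02_t05" %in% colnames(Xo))
  dir5 <- s$events$visual_direction[s$events$block == 2 &
                                      !is.na(s$events$trial) &
                                      s$events$trial == 5]
  col5 <- paste0("b02_", dir5)
  on5 <- s$events$onset[s$events$block == 2 & !is.na(s$events$trial) &
                          s$events$trial == 5]
  scan5 <- floor(on5 / s$timing$tr_s) + 3  # near the response peak
  expect_gt(Xo[scan5, "outlier_b02_t05"], 0)
  expect_lt(Xo[scan5, col5], X[scan5, col5])  # event removed from its column
  # an outlier first trial is modeled once: the null regressor disappears
  tr$outlier[tr$block == 3 & tr$trial == 1] <- TRUE
  X1 <- build_design_matrix(s, trials = tr, variant = "mvpa")
  expect_false("b03_null" %in% colnames(X1))
  expect_true("outlier_b03_t01" %in% colnames(X1))
  # a block of outliers only is degenerate
  tr$outlier[tr$block == 4] <- TRUE
  expect_error(build_design_matrix(s, trials = tr, variant = "mvpa"),
               "block 4")
})

test_that("OLS fit is exact on noiseless data and rejects rank deficiency", {
  s <- build_session(timing = short_timing(), seed = 9)
  X <- build_design_matrix(s, variant = "mvpa")
  set.seed(3)
  B <- matrix(rnorm(ncol(X) * 5), ncol(X), 5)
  Y <- X %*% B
  fit <- fit_glm(Y, X)
  expect_equal(unname(fit$betas), unname(B), tolerance = 1e-9)
  Xdup <- cbind(X, dup = X[, 1])
  attr(Xdup, "column_class") <- c(attr(X, "column_class"), dup = "task")
  expect_error(fit_glm(Y, Xdup), "rank deficient")
})

test_that("pure-noise t statistics follow a central t distribution", {
  s <- build_session(timing = short_timing(), seed = 9)
  X <- build_design_matrix(s, variant = "univariate")
  set.seed(11)
  Y <- matrix(rnorm(nrow(X) * 400), nrow(X))
  fit <- fit_glm(Y, X)
  XtXi <- solve(crossprod(X))
  tstat <- fit$betas["erase_mirror", ] / sqrt(fit$sigma2 * XtXi[3, 3])
  ks <- stats::ks.test(tstat, stats::pt, df = fit$df)
  expect_gt(ks$p.value, 0.01)
})

test_that("OLS recovery is unbiased with nominal interval coverage", {
  s <- build_session(timing = short_timing(), seed = 12)
  X <- build_design_matrix(s, variant = "univariate")
  XtXi <- solve(crossprod(X))
  j <- 1L
  se_scale <- sqrt(XtXi[j, j])
  beta_true <- 0.8
  set.seed(13)
  err <- numeric(50); cover <- logical(50)
  for (r in 1:50) {
    y <- X[, j] * beta_true + rnorm(nrow(X))
    fit <- fit_glm(matrix(y, ncol = 1), X)
    bh <- fit$betas[j, 1]
    se <- sqrt(fit$sigma2[1]) * se_scale
    err[r] <- bh - beta_true
    cover[r] <- abs(err[r]) <= qt(0.975, fit$df) * se
  }
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(50))
  expect_gte(mean(cover), 0.85)  # binomial bounds for 50 draws at 95%
})

test_that("outlier scans are flagged by FD and global-signal rules", {
  n <- 60
  motion <- matrix(0, n, 6)
  gs <- rep(100, n)
  expect_false(any(flag_outlier_scans(motion, gs)))
  # a 2-mm translation level shift flags exactly the jump scan
  motion2 <- motion; motion2[30:n, 1] <- 2
  fl <- flag_outlier_scans(motion2, gs + rnorm(n, 0, 0.01))
  expect_true(fl[30])
  expect_equal(sum(fl), 1)
  expect_equal(framewise_displacement(motion2)[30], 2)
  # rotations count as arc length on a 50-mm sphere
  motion3 <- motion; motion3[10:n, 4] <- 0.02
  expect_equal(framewise_displacement(motion3)[10], 1)
  expect_true(flag_outlier_scans(motion3, gs + rnorm(n, 0, 0.01))[10])
  # a large global spike is flagged (the z-score uses the spiked series'
  # own mean and sd, so the planted excursion must clear 5 SD after
  # inflation)
  set.seed(8)
  gs2 <- rnorm(n)
  gs2[44] <- mean(gs2) + 9 * sd(gs2)
  fl2 <- flag_outlier_scans(motion, gs2)
  expect_true(fl2[44])
  expect_equal(sum(fl2), 1)
})

test_that("Gaussian smoothing preserves mass and matches the kernel", {
  vol <- array(rnorm(10 * 10 * 8), c(10, 10, 8))
  expect_equal(smooth_volume(vol, 0), vol)
  # interior-supported signal keeps its total
  delta <- array(0, c(15, 15, 15)); delta[8, 8, 8] <- 1
  sm <- smooth_volume(delta, 8, 3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # center weight of the delta response equals the normalized separable
  # kernel cubed
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 3
  r <- ceiling(3 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  expect_equal(sm[8, 8, 8], k[r + 1]^3, tolerance = 1e-10)
})
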