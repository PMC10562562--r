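test_that("group GLM t equals the normal-equations oracle", {
  set.seed(1)
  n <- 5
  maps <- matrix(rnorm(n * 6) + 0.5, n, 6)
  confound <- runif(n, 0.2, 1)
  # intercept test with an uncentered confound
  des <- group_design(n, confound = confound, tested = "intercept")
  t_pkg <- group_glm_t(maps, des)
  X <- cbind(1, confound)
  t_ora <- apply(maps, 2, glm_t_oracle, design = X, col = 1)
  expect_equal(t_pkg, t_ora, tolerance = 1e-10)
  # and against lm's own summary on one voxel
  sm <- summary(lm(maps[, 1] ~ confound))
  expect_equal(t_pkg[1], sm$coefficients["(Intercept)", "t value"])
  # covariate (slope) test on a 6-subject toy
  set.seed(2)
  n <- 6
  perf <- rnorm(n, 2, 0.3)
  maps2 <- matrix(10 - 3 * perf + rnorm(n * 4, 0, 0.5), n, 4)
  des2 <- group_design(n, covariate = perf, confound = runif(n),
                       tested = "covariate", alternative = "less")
  t2 <- group_glm_t(maps2, des2)
  X2 <- cbind(1, perf, des2$X[, "confound"])
  t2_ora <- -apply(maps2, 2, glm_t_oracle, design = X2, col = 2)
  expect_equal(t2, t2_ora, tolerance = 1e-10)
  expect_true(all(t2 > 0))  # negative slope, "less" alternative
  # degenerate zero-variance input follows the documented convention
  des0 <- group_design(4, tested = "intercept")
  expect_equal(group_glm_t(matrix(2, 4, 1), des0), Inf)
  expect_equal(group_glm_t(matrix(0, 4, 1), des0), 0)
})

test_that("group designs enforce their preconditions", {
  expect_error(group_design(5, tested = "covariate"), "no covariate")
  expect_error(group_design(5, covariate = 1:3), "length mismatch")
  expect_error(group_design(3, covariate = rep(1, 3)), "rank deficient")
  des <- group_design(6, confound = runif(6), tested = "intercept")
  expect_equal(colnames(des$X), c("intercept", "confound"))
  expect_error(group_glm_t(matrix(0, 3, 2), des), "maps row count")
})

test_that("TFCE matches brute-force threshold summation", {
  # single voxel of height 2 at dh = 0.1: sum of 1^0.5 h^2 dh = 2.87
  vol <- array(0, c(5, 5, 5)); vol[3, 3, 3] <- 2
  out <- tfce(vol, dh = 0.1)
  expect_equal(out[3, 3, 3], 2.87, tolerance = 1e-10)
  expect_equal(sum(out > 0), 1)
  # two-voxel cluster against the independent oracle
  vol2 <- array(0, c(5, 1, 1)); vol2[2:3, 1, 1] <- c(1, 2)
  expect_equal(tfce(vol2, dh = 0.25), tfce_oracle(vol2, dh = 0.25),
               tolerance = 1e-10)
  # random small volumes
  set.seed(4)
  for (r in 1:4) {
    v <- array(pmax(rnorm(4^3, 0.2, 1), 0), c(4, 4, 4))
    expect_equal(tfce(v, dh = max(v) / 25, n_steps = 25),
                 tfce_oracle(v, dh = max(v) / 25), tolerance = 1e-8)
  }
  expect_equal(tfce(array(0, c(3, 3, 3))), array(0, c(3, 3, 3)))
  expect_error(tfce(array(1, c(3, 3, 3)), dh = -1), "positive")
})

test_that("TFCE is monotone in the statistic map", {
  set.seed(5)
  v <- array(pmax(rnorm(5^3, 0.5, 1), 0), c(5, 5, 5))
  t1 <- tfce(v, dh = 0.05)
  bump <- v; bump[2, 2, 2] <- bump[2, 2, 2] + 0.5
  t2 <- tfce(bump, dh = 0.05)
  expect_true(all(t2 - t1 >= -1e-10))
})

test_that("BH q-values follow the step-up rule", {
  p <- c(0.01, 0.04, 0.03, 0.9)
  expect_equal(fdr_bh(p), c(0.04, 0.16 / 3, 0.16 / 3, 0.9))
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))
  p2 <- runif(30)
  expect_true(all(fdr_bh(p2) >= p2))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("permutation p-values respect their discrete bounds", {
  set.seed(6)
  grid <- volume_grid(c(6, 6, 5))
  nv <- sum(grid$mask)
  maps <- matrix(rnorm(8 * nv), 8, nv)
  des <- group_design(8, tested = "intercept")
  g1 <- permutation_fwe(maps, des, grid, statistic = "t", n_perm = 1)
  expect_true(all(g1$p_fwe %in% c(1 / 2, 1)))
  g2 <- permutation_fwe(maps, des, grid, n_perm = 50)
  expect_true(all(g2$p_fwe >= 1 / 51 & g2$p_fwe <= 1))
  expect_true(all(g2$stat >= 0))
  expect_error(permutation_fwe(maps, des, grid, n_perm = 0), "n_perm")
  des_cov <- group_design(8, covariate = rnorm(8), tested = "covariate")
  expect_error(permutation_fwe(maps, des_cov, grid, scheme = "sign_flip"),
               "not a valid scheme")
})

test_that("a strong planted effect is detected and a null is not", {
  set.seed(7)
  grid <- volume_grid(c(8, 8, 6))
  nv <- sum(grid$mask)
  effect <- rep(0, nv); effect[10:14] <- 2.5
  maps <- matrix(rnorm(10 * nv, 0, 1), 10, nv) +
    matrix(effect, 10, nv, byrow = TRUE)
  des <- group_design(10, tested = "intercept")
  gsm <- permutation_fwe(maps, des, grid, n_perm = 200)
  expect_true(any(gsm$p_fwe[10:14] < 0.05))
  expect_lt(mean(gsm$p_fwe < 0.05), 0.05)
  tab <- results_table(gsm)
  expect_gte(nrow(tab), 1)
  expect_true(all(tab$peak_p_fwe < 0.05))
})

test_that("the correlation analysis recovers a planted negative slope", {
  set.seed(8)
  grid <- volume_grid(c(8, 8, 6))
  nv <- sum(grid$mask)
  n <- 12
  perf <- rnorm(n, 2, 0.4)
  slope_map <- rep(0, nv); slope_map[20:26] <- 8
  maps <- 10 - outer(perf, slope_map) + matrix(rnorm(n * nv), n, nv)
  gsm <- accuracy_performance_correlation(maps, perf, grid, n_perm = 300)
  expect_true(any(gsm$p_fwe[20:26] < 0.05))
  expect_lt(sum(gsm$p_fwe[-(20:26)] < 0.05), 0.05 * nv)
  # shuffling the link removes the effect
  gsm0 <- accuracy_performance_correlation(maps, sample(perf), grid,
                                           n_perm = 300)
  expect_gt(min(gsm0$p_fwe), 0.01)
})

test_that("ROI tests reduce to the voxel statistic and the lm oracle", {
  set.seed(9)
  grid <- volume_grid(c(6, 6, 5))
  nv <- sum(grid$mask)
  maps <- matrix(rnorm(5 * nv, 0.4), 5, nv)
  des <- group_design(5, confound = runif(5, 0.2, 0.9),
                      tested = "intercept")
  one <- rep(FALSE, nv); one[7] <- TRUE
  r1 <- roi_test(maps, one, des)
  expect_equal(r1$t, group_glm_t(maps, des)[7], tolerance = 1e-10)
  roi <- rep(FALSE, nv); roi[3:12] <- TRUE
  r2 <- roi_test(maps, roi, des)
  y <- rowMeans(maps[, 3:12])
  sm <- summary(lm(y ~ des$X[, "confound"]))
  expect_equal(r2$t, sm$coefficients["(Intercept)", "t value"],
               tolerance = 1e-10)
  expect_equal(r2$p, pt(r2$t, 3, lower.tail = FALSE))
  expect_equal(roi_test(matrix(0, 5, nv), roi, des)$t, 0)
  expect_error(roi_test(maps, rep(FALSE, nv), des), "empty")
})
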