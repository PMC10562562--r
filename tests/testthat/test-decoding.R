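test_that("pair enumeration matches the printed totals", {
  expect_length(enumerate_pairs("visual"), 12)
  expect_length(enumerate_pairs("movement"), 12)
  expect_length(enumerate_pairs("context_rot_rot"), 8)
  expect_length(enumerate_pairs("context_rot_mirror"), 16)
  # the dedup flag exposes the other counting convention
  expect_length(enumerate_pairs("visual", dedup = TRUE), 6)
  expect_length(enumerate_pairs("context_rot_rot", dedup = FALSE), 16)
  expect_length(enumerate_pairs("context_rot_mirror", dedup = FALSE), 32)
})

test_that("direction-level pairs cross contexts and swap the other level", {
  for (an in c("visual", "movement")) {
    lvl <- paste0(an, "_direction")
    other <- if (an == "visual") "movement_direction" else "visual_direction"
    for (p in enumerate_pairs(an)) {
      expect_false(any(p$train$context %in% p$test$context))
      for (cl in c(-1, 1)) {
        tr <- p$train[p$train$class == cl, ]
        te <- p$test[p$test$class == cl, ]
        expect_equal(tr[[lvl]], te[[lvl]])      # same decoded label
        expect_false(tr[[other]] == te[[other]]) # other level differs
      }
    }
  }
})

test_that("context pairs are matched on one level per side and leak-free", {
  worked <- FALSE
  for (an in c("context_rot_rot", "context_rot_mirror")) {
    for (p in enumerate_pairs(an)) {
      # each side matched on exactly one level
      matched_level <- function(cells)
        c(visual = length(unique(cells$visual_direction)) == 1,
          movement = length(unique(cells$movement_direction)) == 1)
      mtr <- matched_level(p$train); mte <- matched_level(p$test)
      expect_equal(sum(mtr), 1)
      expect_equal(sum(mte), 1)
      expect_false(identical(mtr, mte))
      # no shared (context, direction) cell between train and test
      expect_length(intersect(paste(p$train$context, p$train$visual_direction),
                              paste(p$test$context, p$test$visual_direction)),
                    0)
      # classes label the contexts consistently across both sides
      expect_equal(p$train$context[order(p$train$class)],
                   p$test$context[order(p$test$class)])
      if (an == "context_rot_rot" &&
          all(p$train$visual_direction == "up") &&
          identical(sort(p$test$visual_direction), c("left", "right")))
        worked <- TRUE
    }
  }
  # the worked example: train on upward visual in both rotations, test on
  # rightward visual at -90 with leftward visual at +90
  expect_true(worked)
})

test_that("leave-two-block-out folds partition the repetitions", {
  folds <- leave_two_block_out_folds(5)
  expect_length(folds, 5)
  expect_equal(folds[[1]]$test_rep, 1)
  expect_equal(folds[[1]]$train_reps, 2:5)
  expect_setequal(unlist(lapply(folds, `[[`, "test_rep")), 1:5)
  for (f in folds)
    expect_length(intersect(f$test_rep, f$train_reps), 0)
  expect_error(leave_two_block_out_folds(1), "two repetitions")
})

test_that("decoding jobs never share a (context, direction, block) cell", {
  set.seed(3)
  model <- tiny_model()
  sub <- sample_cohort(2, model)[[1]]
  info <- sub$betas$info
  for (an in analysis_names()) {
    use_folds <- an %in% c("context_rot_rot", "context_rot_mirror")
    jobs <- vmadapt:::.decoding_jobs(info, enumerate_pairs(an), use_folds)
    n_expected <- switch(an, visual = 12, movement = 12,
                         context_rot_rot = 8 * 2 * 5,
                         context_rot_mirror = 16 * 2 * 5)
    expect_length(jobs, n_expected)
    for (j in jobs) {
      tr_cells <- paste(info$context[j$train], info$visual_direction[j$train],
                        info$block[j$train])
      te_cells <- paste(info$context[j$test], info$visual_direction[j$test],
                        info$block[j$test])
      expect_length(intersect(tr_cells, te_cells), 0)
      expect_length(intersect(info$block[j$train], info$block[j$test]), 0)
      expect_setequal(unique(j$train_y), c(-1, 1))
    }
  }
})

test_that("searchlight spheres cover the brute-force offset set", {
  grid <- volume_grid(c(10, 10, 10), mask = array(TRUE, c(10, 10, 10)))
  sp <- searchlight_spheres(grid, 9)
  expect_equal(sp$n_offsets, 123)  # brute-force count at 9 mm / 3 mm voxels
  center <- which(sp$vox_index == (4 * 100 + 4 * 10 + 5))
  expect_equal(sp$counts[center], 123)
  corner <- which(sp$vox_index == 1)
  expect_lt(sp$counts[corner], 123)
  sp0 <- searchlight_spheres(grid, 0)
  expect_true(all(sp0$counts == 1))
  expect_error(searchlight_spheres(grid, -1), ">= 0")
})

test_that("the linear SVM solves hand-checkable problems", {
  # two points on a line: the max-margin boundary sits at the midpoint
  acc <- classify(matrix(c(-1, 1)), c("A", "B"), matrix(0.5), "B")
  expect_equal(as.numeric(acc), 1)
  expect_gt(attr(acc, "decision"), 0)
  acc2 <- classify(matrix(c(-1, 1)), c("A", "B"), matrix(-0.5), "A")
  expect_equal(as.numeric(acc2), 1)
  # separable classes generalize perfectly
  set.seed(4)
  mu <- rnorm(10) * 3
  Xtr <- rbind(matrix(rnorm(50), 5) + rep(mu, each = 5),
               matrix(rnorm(50), 5) - rep(mu, each = 5))
  Xte <- rbind(matrix(rnorm(40), 4) + rep(mu, each = 4),
               matrix(rnorm(40), 4) - rep(mu, each = 4))
  expect_equal(as.numeric(classify(Xtr, rep(c(1, -1), each = 5), Xte,
                                   rep(c(1, -1), each = 4))), 1)
  expect_error(classify(Xtr, rep(1, 10), Xte, rep(1, 8)), "two classes")
  # label-independent features score at chance over many draws
  set.seed(5)
  accs <- replicate(60, {
    classify(matrix(rnorm(8 * 10), 8), rep(c(1, -1), 4),
             matrix(rnorm(20 * 10), 20), sample(c(1, -1), 20, TRUE))
  })
  expect_lt(abs(mean(accs) - 0.5), 2.5 * sqrt(0.25 / (60 * 20)) + 0.03)
})

test_that("the SVM agrees with the libsvm reference implementation", {
  set.seed(2)
  for (r in 1:10) {
    p <- 15
    mu <- rnorm(p) * 1.5
    Xtr <- matrix(rnorm(10 * p), 10, p) +
      outer(rep(c(1, -1), each = 5), mu)
    ytr <- rep(c(1, -1), each = 5)
    fit <- vmadapt:::cpp_svm_train(Xtr, ytr, 1)
    sv <- e1071::svm(Xtr, factor(ytr, levels = c(1, -1)), kernel = "linear",
                     cost = 1, scale = FALSE)
    w_ref <- as.numeric(t(sv$coefs) %*% sv$SV)
    w_ours <- as.numeric(fit$w)
    cosine <- sum(w_ours * w_ref) /
      sqrt(sum(w_ours^2) * sum(w_ref^2))
    expect_gt(cosine, 0.95)
    Xte <- matrix(rnorm(40 * p), 40, p) + outer(rep(c(1, -1), each = 20), mu)
    yte <- rep(c(1, -1), each = 20)
    acc_ours <- mean(sign(as.numeric(
      vmadapt:::cpp_svm_decision(Xte, fit$w, fit$b))) == yte)
    acc_ref <- mean(as.numeric(as.character(predict(sv, Xte))) == yte)
    expect_equal(acc_ours, acc_ref)
  }
})

test_that("searchlight maps localize the planted signal", {
  set.seed(12)
  model <- tiny_model()
  sub <- sample_cohort(2, model)[[1]]
  sp <- searchlight_spheres(model$grid, 3)
  grid <- model$grid
  am <- run_searchlight_decoding(sub, "visual", decoding_config(radius_mm = 3),
                                 sp)
  expect_true(all(am$values >= -50 & am$values <= 50))
  expect_gt(mean(am$values[model$regions$visual_region[grid$mask]]), 5)
  expect_lt(abs(mean(am$values[model$regions$null_region[grid$mask]])), 12)
  # deterministic given the subject and config
  am2 <- run_searchlight_decoding(sub, "visual", decoding_config(), sp)
  expect_identical(am$values, am2$values)
  # ROI restriction leaves other centers NA
  roi <- model$regions$visual_region
  am3 <- run_searchlight_decoding(sub, "visual", decoding_config(), sp,
                                  roi_mask = roi)
  expect_true(all(is.na(am3$values[!roi[grid$mask]])))
  expect_equal(am3$values[roi[grid$mask]], am$values[roi[grid$mask]])
})

test_that("preparation decoding uses 5 and 10 leave-two-out folds", {
  set.seed(13)
  model <- tiny_model()
  sub <- sample_cohort(2, model)[[1]]
  sp <- searchlight_spheres(model$grid, 9)
  info <- sub$betas$info
  grid <- model$grid
  pm <- preparation_decoding(sub, "rot_rot", decoding_config(), sp)
  expect_equal(pm$n_tests, 5 * 2)       # 5 folds x 2 test blocks
  pm2 <- preparation_decoding(sub, "rot_mirror", decoding_config(), sp)
  expect_equal(pm2$n_tests, 10 * 2)     # 10 folds x 2 test blocks
  expect_gt(mean(pm2$values[model$regions$context_region[grid$mask]]), 0)
  # identical preparation patterns across contexts decode at chance
  sub2 <- sub
  prep_cols <- which(info$regressor == "prep")
  base <- sub2$betas$coefficients[, prep_cols[1]]
  sub2$betas$coefficients[, prep_cols] <-
    base + matrix(rnorm(length(base) * length(prep_cols), 0, 0.01),
                  ncol = length(prep_cols))
  pm3 <- preparation_decoding(sub2, "rot_rot", decoding_config(), sp)
  expect_lt(abs(mean(pm3$values)), 15)
  sub3 <- sub
  sub3$betas$info <- info[info$regressor != "prep", ]
  sub3$betas$coefficients <- sub3$betas$coefficients[, info$regressor != "prep"]
  expect_error(preparation_decoding(sub3, "rot_rot", decoding_config(), sp),
               "preparation betas")
})

test_that("the fold-free variant matches the correlation-analysis bookkeeping", {
  set.seed(14)
  model <- tiny_model()
  sub <- sample_cohort(2, model)[[1]]
  jobs_folds <- vmadapt:::.decoding_jobs(sub$betas$info,
                                         enumerate_pairs("context_rot_rot"),
                                         TRUE)
  jobs_flat <- vmadapt:::.decoding_jobs(sub$betas$info,
                                        enumerate_pairs("context_rot_rot"),
                                        FALSE)
  expect_length(jobs_folds, 80)
  expect_length(jobs_flat, 16)   # 8 pairs x both directions, no folds
  jobs_flat_m <- vmadapt:::.decoding_jobs(sub$betas$info,
                                          enumerate_pairs("context_rot_mirror"),
                                          FALSE)
  expect_length(jobs_flat_m, 32) # 16 pairs x both directions
})

test_that("pair audit tables expose every cell", {
  tab <- pair_audit_table("context_rot_mirror")
  expect_equal(nrow(tab), 16 * 4)  # 16 pairs x (2 train + 2 test cells)
  expect_setequal(unique(tab$role), c("train", "test"))
  path <- tempfile(fileext = ".tsv")
  pair_audit_table("visual", path)
  expect_true(file.exists(path))
  expect_equal(nrow(utils::read.table(path, header = TRUE, sep = "\t")),
               12 * 4)
})
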