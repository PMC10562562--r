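test_that("direction labels follow the y-down screen convention", {
  dl <- direction_labels()
  expect_setequal(dl$name, c("up", "down", "left", "right"))
  expect_equal(direction_vector("up"), c(0, -1))
  expect_equal(direction_vector("right"), c(1, 0))
  for (d in dl$name)
    expect_equal(direction_vector(opposite_direction(d)),
                 -direction_vector(d))
})

test_that("context matrices match the printed transforms and invert", {
  ct <- context_transforms()
  expect_equal(ct$rot_minus90$matrix, matrix(c(0, -1, 1, 0), 2, 2))
  expect_equal(ct$rot_plus90$matrix, matrix(c(0, 1, -1, 0), 2, 2))
  expect_equal(ct$mirror$matrix, matrix(c(-1, 0, 0, 1), 2, 2))
  for (cx in ct) {
    expect_equal(cx$matrix %*% cx$inverse, diag(2))
    det_expected <- if (cx$name == "mirror") -1 else 1
    expect_equal(det(cx$matrix), det_expected)
  }
  expect_equal(ct$mirror$matrix, ct$mirror$inverse)
})

test_that("required movements reproduce the worked correspondences", {
  expect_equal(required_movement("rot_minus90", "up"), "right")
  expect_equal(required_movement("mirror", "up"), "up")
  expect_equal(required_movement("rot_plus90", "up"), "left")
  expect_equal(required_movement("mirror", "left"), "right")
  # round trip: transforming the required movement recovers the visual
  # direction, for every context and direction
  for (cx in context_names()) for (d in direction_labels()$name) {
    mv <- required_movement(cx, d)
    expect_equal(apply_context_transform(cx, direction_vector(mv)),
                 direction_vector(d))
    expect_equal(visual_of_movement(cx, mv), d)
  }
  # the two rotations demand opposite movements for every visual direction
  for (d in direction_labels()$name)
    expect_equal(required_movement("rot_plus90", d),
                 opposite_direction(required_movement("rot_minus90", d)))
})

test_that("cursor transforms act as printed on hand displacements", {
  expect_equal(apply_context_transform("mirror", c(1, 0)), c(-1, 0))
  expect_equal(apply_context_transform("mirror", c(0, 1)), c(0, 1))
  expect_equal(apply_context_transform("rot_minus90", c(1, 0)), c(0, -1))
  expect_error(apply_context_transform("mirror", c(NA, 0)), "finite")
})

test_that("carryover sequences are serially balanced", {
  expect_equal(carryover_template(),
               c(1, 2, 2, 3, 4, 4, 1, 1, 3, 3, 1, 4, 2, 4, 3, 2, 1))
  # identity label map returns the template itself
  expect_equal(generate_carryover_sequence(4, label_map = 1:4),
               carryover_template())
  # the template's 16 transitions cover each ordered pair exactly once
  expect_true(all(transition_counts(carryover_template(), 4) == 1L))
  set.seed(21)
  for (r in 1:5) {
    s <- generate_carryover_sequence(4)
    expect_length(s, 17)
    expect_true(all(transition_counts(s, 4) == 1L))
    counts <- tabulate(s, 4)
    expect_true(all(counts >= 4))
    expect_equal(sum(counts == 5), 1)
  }
  # general n via the Eulerian construction
  for (n in c(2, 3, 5)) {
    s <- generate_carryover_sequence(n)
    expect_length(s, n^2 + 1)
    expect_true(all(transition_counts(s, n) == 1L))
  }
  expect_error(generate_carryover_sequence(1), ">= 2")
})

test_that("direction assignment is a balanced bijection", {
  tpl <- carryover_template()
  seq_id <- assign_directions(tpl, mapping = c("up", "down", "left", "right"))
  counts <- table(seq_id)
  expect_equal(min(counts), 4)
  expect_equal(max(counts), 5)
  set.seed(4)
  a1 <- assign_directions(tpl)
  a2 <- assign_directions(tpl)
  expect_false(identical(a1, a2))
  expect_equal(sort(as.numeric(table(a1))), sort(as.numeric(table(a2))))
  expect_error(assign_directions(tpl, mapping = c("up", "up", "left", "right")),
               "permutation")
})

test_that("sessions carry 15 balanced blocks with ordered events", {
  s <- build_session(seed = 7)
  expect_length(s$blocks, 15)
  ctx <- vapply(s$blocks, `[[`, "", "context")
  expect_equal(as.numeric(table(ctx)[context_names()]), rep(5, 3))
  for (blk in s$blocks) {
    expect_length(blk$trial_sequence, 17)
    idx <- match(blk$trial_sequence, direction_labels()$name)
    expect_true(all(transition_counts(idx, 4) == 1L))
  }
  ev <- s$events
  expect_true(all(diff(ev$onset) > 0))
  # non-overlapping events
  expect_true(all(ev$onset[-1] >= (ev$onset + ev$duration)[-nrow(ev)]))
  # each block: one preparation before trial 1, one score after trial 17
  for (b in 1:15) {
    evb <- ev[ev$block == b, ]
    expect_equal(evb$trial_type[1], "preparation")
    expect_equal(sum(evb$trial_type == "trial"), 17)
    expect_equal(evb$trial_type[nrow(evb) - 1L], "score")
    expect_equal(evb$trial_type[nrow(evb)], "termination")
  }
  s2 <- build_session(seed = 8)
  expect_false(identical(vapply(s2$blocks, `[[`, "", "context"), ctx))
})

test_that("events tables round-trip through the tab-separated dialect", {
  s <- build_session(seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_events(s, path)
  ev <- read_events(path)
  expect_equal(ev$onset, s$events$onset)
  expect_equal(ev$visual_direction, s$events$visual_direction)
  writeLines("onset\tduration\n0\t1", path)
  expect_error(read_events(path), "lacks columns")
})
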