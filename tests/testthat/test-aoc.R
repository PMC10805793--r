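test_that("serial prediction is the straight segment between its endpoints", {
  cv <- serial_prediction(0.9, 0.8)
  expect_equal(drop(cv$locus(1)), c(acc_bottom = 0.5, acc_top = 0.9))
  expect_equal(drop(cv$locus(0)), c(acc_bottom = 0.8, acc_top = 0.5))
  mid <- serial_prediction(0.8, 0.8)$locus(0.5)
  expect_equal(drop(mid), c(acc_bottom = 0.65, acc_top = 0.65))
  # chance anchors collapse to a point
  flat <- serial_prediction(0.5, 0.5)$locus(seq(0, 1, 0.25))
  expect_true(all(flat == 0.5))
})

test_that("fixed-capacity locus matches the sample-size closed form", {
  cv <- fixed_capacity_prediction(0.8, 0.8)
  q <- drop(cv$locus(0.5))
  expect_equal(unname(q[1]), pnorm(qnorm(0.8) / sqrt(2)), tolerance = 1e-12)
  expect_equal(unname(q[2]), pnorm(qnorm(0.8) / sqrt(2)), tolerance = 1e-12)
  # zero share on one side drops that side to chance
  expect_equal(drop(cv$locus(1)), c(acc_bottom = 0.5, acc_top = 0.8))
  expect_warning(fixed_capacity_prediction(1, 0.8), "clamped")
})

test_that("serial and fixed-capacity loci share both endpoints exactly", {
  for (anchors in list(c(0.9, 0.8), c(0.7, 0.85), c(0.8, 0.8))) {
    ser <- serial_prediction(anchors[1], anchors[2])
    fix <- fixed_capacity_prediction(anchors[1], anchors[2])
    expect_equal(drop(ser$locus(0)), drop(fix$locus(0)), tolerance = 1e-12)
    expect_equal(drop(ser$locus(1)), drop(fix$locus(1)), tolerance = 1e-12)
  }
})

test_that("model dominance: independent >= fixed-capacity >= serial", {
  w <- seq(0, 1, length.out = 101)
  for (anchors in list(c(0.9, 0.8), c(0.75, 0.75), c(0.85, 0.95))) {
    ser <- serial_prediction(anchors[1], anchors[2])$locus(w)
    fix <- fixed_capacity_prediction(anchors[1], anchors[2])$locus(w)
    ind <- drop(independent_prediction(anchors[1], anchors[2])$locus(0))
    expect_true(all(fix >= ser - 1e-12))
    expect_true(all(fix[, 1] <= ind[1] + 1e-12))
    expect_true(all(fix[, 2] <= ind[2] + 1e-12))
  }
})

test_that("signed distance to the serial segment matches the analytic form", {
  a <- 0.8
  ser <- serial_prediction(a, a)
  # independent point vs serial line: point-to-line distance (a - 0.5)/sqrt(2)
  res <- signed_distance(aoc_point(a, a), ser)
  expect_equal(res$signed_distance, (a - 0.5) / sqrt(2), tolerance = 1e-9)
  # a point on the segment has zero distance and recovers its parameter
  on_line <- drop(ser$locus(0.3))
  res0 <- signed_distance(aoc_point(on_line[1], on_line[2]), ser)
  expect_equal(res0$signed_distance, 0, tolerance = 1e-9)
  expect_equal(res0$param_hat, 0.3, tolerance = 1e-6)
  # a point inside the segment has negative distance
  res_in <- signed_distance(aoc_point(0.55, 0.55), ser)
  expect_lt(res_in$signed_distance, 0)
})

test_that("serial endpoint projection pins p_top_hat to 1", {
  ser <- serial_prediction(0.85, 0.8)
  res <- signed_distance(aoc_point(0.5, 0.85), ser)
  expect_equal(res$param_hat, 1, tolerance = 1e-6)
  expect_equal(res$signed_distance, 0, tolerance = 1e-9)
})

test_that("distance to the independent point is the plain Euclidean distance", {
  ind <- independent_prediction(0.8, 0.9)
  expect_equal(signed_distance(aoc_point(0.9, 0.8), ind)$signed_distance, 0,
               tolerance = 1e-12)
  res <- signed_distance(aoc_point(0.7, 0.6), ind)
  expect_equal(abs(res$signed_distance),
               sqrt((0.9 - 0.7)^2 + (0.8 - 0.6)^2), tolerance = 1e-9)
  expect_lt(res$signed_distance, 0)
})

test_that("distance is invariant to swapping the top/bottom labels", {
  dual <- aoc_point(0.62, 0.71)
  swapped <- aoc_point(0.71, 0.62)
  for (fn in list(serial_prediction, fixed_capacity_prediction,
                  independent_prediction)) {
    d1 <- signed_distance(dual, fn(0.85, 0.78))$signed_distance
    d2 <- signed_distance(swapped, fn(0.78, 0.85))$signed_distance
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("aoc_summary recovers the generating geometry per regime", {
  design <- trial_design(60)
  ind <- aoc_summary(simulate_experiment(6, study_observer("independent"),
                                         design, seed = 11))
  expect_equal(mean(ind$dist_independent), 0, tolerance = 0.02)

  ser <- aoc_summary(simulate_experiment(6, study_observer("serial", p_top = 0.74),
                                         design, seed = 12))
  expect_equal(mean(ser$dist_serial), 0, tolerance = 0.03)
  expect_equal(mean(ser$p_top_hat), 0.74, tolerance = 0.05)
  # serial data lie inside the fixed-capacity curve
  expect_lt(mean(ser$dist_fixed_capacity), -0.03)
})

test_that("subjects missing a condition are excluded with a warning", {
  p <- study_observer("serial")
  good <- simulate_observer(p, trial_design(20), seed = 1, subject = "ok")
  bad <- good[good$cue == "dual", ]
  bad$subject <- "incomplete"
  expect_warning(res <- aoc_summary(dplyr::bind_rows(good, bad)), "incomplete")
  expect_equal(res$subject, "ok")
})
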