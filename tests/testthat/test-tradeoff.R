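test_that("serial trade-off matches the closed-form conditional accuracies", {
  # serial observer, p_top = 0.5, single-task PC = 0.8:
  # P(correct | other incorrect) = 0.25 / (0.75 - 0.5 * 0.8) = 5/7
  # P(correct | other correct)   = 0.4 / 0.65             = 8/13
  p <- study_observer("serial", p_top = 0.5)
  tr <- simulate_observer(p, trial_design(600), seed = 21)  # 6,000 dual trials
  res <- tradeoff_analysis(tr)
  expect_equal(res$pc_other_incorrect, 5 / 7, tolerance = 0.02)
  expect_equal(res$pc_other_correct, 8 / 13, tolerance = 0.02)
  expect_gt(res$difference, 0)
  expect_false(res$flagged)
})

test_that("the partition is exhaustive over scored dual responses", {
  p <- study_observer("serial", p_top = 0.6)
  tr <- simulate_observer(p, trial_design(40), seed = 22)
  res <- tradeoff_analysis(tr)
  n_dual <- sum(tr$cue == "dual")
  expect_equal(res$n_other_incorrect + res$n_other_correct, 2 * n_dual)
})

test_that("parallel observers show no trade-off", {
  for (regime in c("fixed_capacity", "independent")) {
    tr <- simulate_observer(study_observer(regime), trial_design(600),
                            seed = 23)
    res <- tradeoff_analysis(tr)
    expect_equal(res$difference, 0, tolerance = 0.025)
  }
})

test_that("unprocessed responses sit at chance A_g", {
  p <- study_observer("serial", p_top = 1)
  tr <- simulate_observer(p, trial_design(600), seed = 24)
  dual <- tr[tr$cue == "dual", ]
  expect_equal(ag_for(dual, "bottom"), 0.5, tolerance = 0.02)
})

test_that("degenerate partitions are flagged", {
  # all top responses correct -> the bottom side's other-incorrect set is empty
  n <- 40
  tr <- tibble::tibble(
    subject = "s01", block = 1L, trial = seq_len(n), cue = "dual",
    cat_top = rep(c("present", "absent"), n / 2),
    cat_bottom = rep(c("present", "absent"), each = n / 2),
    resp_top = rep(c(4L, 1L), n / 2),  # always correct
    resp_bottom = rep(c(4L, 1L), each = n / 2),
    first_response_side = "top", isi_ms = 84, fixation_break = FALSE
  )
  expect_warning(res <- tradeoff_analysis(tr), "degenerate")
  expect_true(res$flagged)
})

test_that("the serial trade-off curve grows away from the identity line", {
  curve <- serial_tradeoff_curve(c(0.6, 0.7, 0.8, 0.9), p_top = 0.5,
                                 n_dual_trials = 20000, seed = 25)
  expect_true(all(diff(curve$difference) > 0))
  expect_true(all(curve$difference > 0))
  # towards chance the curve meets the identity line
  low <- serial_tradeoff_curve(0.52, p_top = 0.5, n_dual_trials = 20000,
                               seed = 26)
  expect_lt(abs(low$ag_other_incorrect - low$ag_other_correct), 0.02)
  expect_lt(abs(low$ag_other_incorrect - 0.5), 0.02)
})

test_that("a fixed-capacity observer run through the curve machinery sits on the identity line", {
  p <- study_observer("fixed_capacity")
  tr <- simulate_observer(p, trial_design(600), seed = 27)
  res <- tradeoff_analysis(tr)
  expect_equal(res$ag_other_incorrect, res$ag_other_correct, tolerance = 0.025)
})
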