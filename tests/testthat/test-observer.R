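test_that("trial structure follows the block design", {
  p <- study_observer("serial")
  tr <- simulate_observer(p, trial_design(n_blocks = 12, trials_per_block = 20),
                          seed = 1)
  expect_equal(nrow(tr), 240)
  # sets of four blocks: two dual, one single per side
  expect_equal(sum(tr$cue == "dual"), 120)
  expect_equal(sum(tr$cue == "single_top"), 60)
  expect_equal(sum(tr$cue == "single_bottom"), 60)

  dual <- tr[tr$cue == "dual", ]
  expect_false(anyNA(dual$resp_top))
  expect_false(anyNA(dual$resp_bottom))
  expect_true(all(dual$first_response_side %in% c("top", "bottom")))
  st <- tr[tr$cue == "single_top", ]
  expect_false(anyNA(st$resp_top))
  expect_true(all(is.na(st$resp_bottom)))
  expect_true(all(is.na(st$first_response_side)))

  expect_identical(tr, simulate_observer(
    p, trial_design(n_blocks = 12, trials_per_block = 20), seed = 1))
})

test_that("stimulus categories are independent across sides", {
  p <- study_observer("independent")
  tr <- simulate_observer(p, trial_design(200), seed = 2)
  ct <- tr$cat_top == "present"
  cb <- tr$cat_bottom == "present"
  expect_equal(mean(ct), 0.5, tolerance = 0.03)
  expect_equal(mean(cb), 0.5, tolerance = 0.03)
  expect_lt(abs(cor(ct, cb)), 0.05)
})

test_that("serial observer processes the top side with probability p_top", {
  p <- study_observer("serial", p_top = 0.74)
  tr <- simulate_observer(p, trial_design(400), seed = 3)
  dual <- tr[tr$cue == "dual", ]
  expect_equal(mean(dual$proc_top), 0.74, tolerance = 0.015)
  expect_true(all(xor(dual$proc_top, dual$proc_bottom)))
})

test_that("single-task proportion correct matches pnorm(dprime/2)", {
  for (regime in c("serial", "fixed_capacity", "independent")) {
    p <- observer_params(regime, dprime_top = 1.19)
    tr <- simulate_observer(p, trial_design(600), seed = 4)
    st <- tr[tr$cue == "single_top", ]
    pc <- mean((st$resp_top >= 3) == (st$cat_top == "present"))
    expect_lt(abs(pc - pnorm(1.19 / 2)), 0.02)
  }
})

test_that("guessed responses carry no signal", {
  # p_top = 1: the bottom response on dual trials is always a guess
  p <- study_observer("serial", p_top = 1)
  tr <- simulate_observer(p, trial_design(400), seed = 5)
  dual <- tr[tr$cue == "dual", ]
  pc_bottom <- mean((dual$resp_bottom >= 3) == (dual$cat_bottom == "present"))
  expect_equal(pc_bottom, 0.5, tolerance = 0.02)
  expect_equal(ag_for(dual, "bottom"), 0.5, tolerance = 0.02)
  # also when guess_dist is supplied explicitly and rating-symmetric
  p2 <- study_observer("serial", p_top = 1, guess_dist = c(0, 0.5, 0.5, 0))
  tr2 <- simulate_observer(p2, trial_design(400), seed = 6)
  dual2 <- tr2[tr2$cue == "dual", ]
  pc2 <- mean((dual2$resp_bottom >= 3) == (dual2$cat_bottom == "present"))
  expect_equal(pc2, 0.5, tolerance = 0.02)
})

test_that("independent observer shows no dual-task deficit", {
  p <- study_observer("independent")
  tr <- simulate_observer(p, trial_design(400), seed = 7)
  expect_equal(ag_for(tr, "top", "dual"), ag_for(tr, "top", "single_top"),
               tolerance = 0.02)
  expect_equal(ag_for(tr, "bottom", "dual"),
               ag_for(tr, "bottom", "single_bottom"), tolerance = 0.02)
})

test_that("fixed-capacity observer splits sensitivity on dual trials", {
  p <- study_observer("fixed_capacity", w_top = 0.5)
  tr <- simulate_observer(p, trial_design(400), seed = 8)
  dual <- tr[tr$cue == "dual", ]
  pc_dual <- mean((dual$resp_top >= 3) == (dual$cat_top == "present"))
  d_eff <- dprime_for_pc(0.8) * sqrt(0.5)
  expect_equal(pc_dual, pnorm(d_eff / 2), tolerance = 0.02)
})

test_that("selection errors swap the two sides' reports", {
  p <- study_observer("serial", selection_error_rate = 1)
  tr <- simulate_observer(p, trial_design(200), seed = 9)
  # on single-task trials the observer reported the wrong side's stimulus:
  # accuracy scored against the cued side's category is at chance
  st <- tr[tr$cue == "single_top", ]
  pc_cued <- mean((st$resp_top >= 3) == (st$cat_top == "present"))
  expect_equal(pc_cued, 0.5, tolerance = 0.03)
  # ... but scored against the other side's category it is intact
  pc_other <- mean((st$resp_top >= 3) == (st$cat_bottom == "present"))
  expect_equal(pc_other, 0.8, tolerance = 0.03)
})

test_that("invalid observer parameters are rejected", {
  expect_error(observer_params("serial", criteria = c(1, 0, -1)))
  expect_error(observer_params("diffusion"))
  expect_error(observer_params("serial", guess_dist = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(observer_params("serial", p_top = 1.5))
})
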