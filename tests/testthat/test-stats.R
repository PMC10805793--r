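test_that("bootstrap CI is seeded, degenerate on constants, and covers", {
  expect_equal(bootstrap_ci(rep(3, 10), seed = 1), c(3, 3))
  x <- rnorm(20)
  expect_identical(bootstrap_ci(x, seed = 5), bootstrap_ci(x, seed = 5))
  expect_error(bootstrap_ci(1), "at least 2")

  # empirical coverage of the true mean over replicate datasets
  set.seed(99)
  n_rep <- 300
  covered <- vapply(seq_len(n_rep), function(i) {
    x <- rnorm(30)
    ci <- bootstrap_ci(x, n_boot = 400, seed = i)
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  set.seed(11)
  width <- vapply(c(25, 400), function(n) {
    ci <- bootstrap_ci(rnorm(n), n_boot = 2000, seed = 3)
    ci[2] - ci[1]
  }, numeric(1))
  expect_equal(width[1] / width[2], 4, tolerance = 0.35)
})

test_that("one-sample t matches the longhand formula", {
  set.seed(8)
  x <- rnorm(11, mean = 0.5)
  res <- one_sample_t(x)
  t_long <- mean(x) / (sd(x) / sqrt(11))
  expect_equal(res$t, t_long, tolerance = 1e-12)
  expect_equal(res$df, 10L)
  expect_equal(res$p, 2 * pt(-abs(t_long), df = 10), tolerance = 1e-12)
  expect_error(one_sample_t(c(1, 1, 1)), "zero variance")

  y <- c(-2, -1, 0, 1, 2)
  res0 <- one_sample_t(y)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
})

test_that("jzs_bf agrees with an independent Cauchy-prior integration", {
  for (case in list(c(2.2, 15), c(0.5, 8), c(4.51, 11), c(3.3, 30))) {
    expect_equal(jzs_bf(case[1], case[2]),
                 jzs_bf_oracle(case[1], case[2]), tolerance = 1e-5)
  }
  # and with a non-default prior scale
  expect_equal(jzs_bf(2.5, 12, r = 1), jzs_bf_oracle(2.5, 12, r = 1),
               tolerance = 1e-5)
})

test_that("jzs_bf favors the null at t = 0 and grows with |t|", {
  expect_lt(jzs_bf(0, 11), 1)
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, jzs_bf, numeric(1), n = 11)
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_bf(-3, 11), jzs_bf(3, 11), tolerance = 1e-9)
})

test_that("effect_test bundles t, bootstrap CI and BF coherently", {
  set.seed(30)
  x <- rnorm(11, mean = 1)
  res <- effect_test(x, seed = 2)
  expect_s3_class(res, "stat_result")
  expect_lte(res$ci_low, res$mean_diff)
  expect_gte(res$ci_high, res$mean_diff)
  expect_equal(res$bf, jzs_bf(res$t, 11), tolerance = 1e-10)
  expect_identical(res$df, 10L)
})

test_that("rm interaction test separates additive from crossover tables", {
  subjects <- sprintf("s%02d", 1:11)
  grid <- expand.grid(subject = subjects, f1 = c("a1", "a2"),
                      f2 = c("b1", "b2"), stringsAsFactors = FALSE)
  # additive: no interaction beyond noise
  set.seed(41)
  grid$value <- 0.1 * (grid$f1 == "a2") + 0.2 * (grid$f2 == "b2") +
    rnorm(nrow(grid), sd = 0.05)
  res_add <- rm_interaction_test(grid)
  expect_gt(res_add$p, 0.05)
  expect_equal(res_add$df1, 1)
  expect_equal(res_add$df2, 10)
  # pure crossover: large interaction
  grid$value <- ifelse(xor(grid$f1 == "a2", grid$f2 == "b2"), 0.3, -0.3) +
    rnorm(nrow(grid), sd = 0.05)
  res_cross <- rm_interaction_test(grid)
  expect_lt(res_cross$p, 0.05)
  expect_gt(res_cross$F, res_add$F)

  expect_error(rm_interaction_test(grid[-1, ]), "incomplete")
})

test_that("rm interaction p values are approximately uniform under the null", {
  subjects <- sprintf("s%02d", 1:8)
  grid <- expand.grid(subject = subjects, f1 = c("a1", "a2"),
                      f2 = c("b1", "b2"), stringsAsFactors = FALSE)
  set.seed(55)
  pvals <- vapply(seq_len(250), function(i) {
    grid$value <- rnorm(nrow(grid))
    rm_interaction_test(grid)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
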