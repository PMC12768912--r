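test_that("cohorts are bit-reproducible and carry full ground truth", {
  a <- generate_cohort(n_participants = 4, seed = 11, n_blocks = 1)
  b <- generate_cohort(n_participants = 4, seed = 11, n_blocks = 1)
  expect_identical(a$trials, b$trials)
  expect_identical(a$glucose, b$glucose)
  expect_identical(a$ground_truth, b$ground_truth)

  co <- generate_cohort(n_participants = 48, seed = 2, n_blocks = 1)
  expect_equal(nrow(co$ground_truth), 48)
  expect_true(all(c("alpha_reward", "alpha_loss", "beta", "true_iauc",
                    "fasting") %in% names(co$ground_truth)))
  expect_true(all(co$ground_truth$alpha_reward > 0 &
                    co$ground_truth$alpha_reward < 1))
  expect_true(all(co$ground_truth$beta > 0))
})

test_that("planted correlations are recovered in large samples", {
  gp <- cohort_group_params()
  tr <- glycolearn:::cohort_latents(2000, gp, planted_correlations(), 13)
  expect_lt(abs(cor(tr$alpha_reward, tr$true_iauc) - 0.32), 0.05)
  expect_lt(abs(cor(tr$alpha_reward, tr$phq9) - 0.18), 0.05)
  tr0 <- glycolearn:::cohort_latents(2000, gp, planted_correlations(0, 0, 0),
                                     13)
  expect_lt(abs(cor(tr0$alpha_reward, tr0$true_iauc)), 0.05)
  expect_lt(abs(cor(tr0$alpha_reward, tr0$phq9)), 0.05)
})

test_that("measured iAUC tracks the planted ground truth", {
  co <- generate_cohort(n_participants = 12, seed = 4, n_blocks = 1)
  gs <- summarize_glucose(co$glucose)
  gs <- gs[match(co$ground_truth$participant_id, gs$participant_id), ]
  expect_gt(cor(gs$iauc, co$ground_truth$true_iauc), 0.95)
  expect_lt(max(abs(gs$fasting - co$ground_truth$fasting)), 1)
})

test_that("invalid planted matrices are rejected", {
  bad <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3, 3)
  expect_error(generate_cohort(n_participants = 4, planted = bad, seed = 1),
               "positive definite|too strong")
  expect_error(generate_cohort(n_participants = 1, seed = 1), "at least 2")
})

test_that("affect ratings follow the configured trends", {
  aff <- simulate_affect_trajectory(57.6, -0.08, 0, n_trials = 360, seed = 1,
                                    affect_type = "happiness")
  expect_equal(aff$affect_rating[1], 57.6)
  expect_equal(aff$affect_rating[360], 57.6 - 0.08 * 359)
  # least-squares recovery of the generating slope from noiseless output
  fit <- lm(affect_rating ~ I(trial - 1), data = aff)
  expect_equal(unname(coef(fit)[2]), -0.08, tolerance = 1e-10)

  flat <- simulate_affect_trajectory(50, 0, 0, n_trials = 10, seed = 1)
  expect_true(all(flat$affect_rating == 50))
  expect_error(simulate_affect_trajectory(120, 0, 1, 10, 1), "start_percent")
})
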