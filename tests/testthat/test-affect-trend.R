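noiseless_cohort_trials <- function(slope, start = 57.6, n_participants = 4,
                                    n_trials = 120) {
  purrr::map_dfr(seq_len(n_participants), function(i) {
    aff <- simulate_affect_trajectory(start, slope, 0, n_trials,
                                      seed = i, affect_type = "happiness")
    tibble::tibble(
      participant_id = sprintf("P%02d", i), phase = "training", block = 1L,
      trial = aff$trial, left_symbol = "A", right_symbol = "B",
      chosen_symbol = "A", outcome = 1,
      affect_type = aff$affect_type, affect_rating = aff$affect_rating
    )
  })
}

test_that("the generating trend is recovered from noiseless ratings", {
  tr <- noiseless_cohort_trials(slope = -0.08)
  fit <- affect_trend(tr, "happiness", seed = 1, chains = 2, iter = 400)
  fx <- tidy(fit)
  expect_equal(fx$estimate[fx$term == "trial"], -0.08, tolerance = 0.01)
  expect_equal(fx$estimate[fx$term == "(Intercept)"], 57.6, tolerance = 1)
})

test_that("zero-slope data leave the slope HDI spanning zero", {
  set.seed(9)
  tr <- noiseless_cohort_trials(slope = 0, n_participants = 6)
  tr$affect_rating <- tr$affect_rating + rnorm(nrow(tr), 0, 8)
  fit <- affect_trend(tr, "happiness", seed = 2, chains = 2, iter = 400)
  fx <- tidy(fit)
  sl <- fx[fx$term == "trial", ]
  expect_lte(sl$hdi90_lower, 0)
  expect_gte(sl$hdi90_upper, 0)
})

test_that("a duplicated shared trajectory matches ordinary least squares", {
  tr <- noiseless_cohort_trials(slope = -0.2, n_participants = 3,
                                n_trials = 60)
  fit <- affect_trend(tr, "happiness", seed = 3, chains = 2, iter = 400)
  ols <- lm(affect_rating ~ I(trial - 1), data = tr)
  fx <- tidy(fit)
  expect_equal(fx$estimate[fx$term == "trial"], unname(coef(ols)[2]),
               tolerance = 0.02)
})

test_that("a moderator adds an interaction term", {
  tr <- noiseless_cohort_trials(slope = -0.1, n_participants = 6)
  mod <- setNames(rnorm(6), sprintf("P%02d", 1:6))
  fit <- affect_trend(tr, "happiness", seed = 4, moderator = mod,
                      chains = 2, iter = 300)
  expect_true("trial:moderator" %in% tidy(fit)$term)
})

test_that("missing rating types are an error", {
  tr <- noiseless_cohort_trials(slope = 0)
  expect_error(affect_trend(tr, "engagement", seed = 1), "no ratings")
})
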