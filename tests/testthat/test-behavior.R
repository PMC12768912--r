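probs6 <- setNames(c(.8, .2, .7, .3, .6, .4), LETTERS[1:6])

test_that("deterministic stay and shift policies hit the rate bounds", {
  # same pair shown 6 times; rewarded choices always repeated
  stay <- make_trials(rep("A", 6), c(1, 1, 0, 1, 1, 1),
                      rep("A", 6), rep("B", 6))
  s <- behavioral_summaries(stay, reward_probs = probs6)
  expect_equal(s$win_stay, 1.0)
  expect_equal(s$lose_shift, 0.0) # stayed after the loss too

  shift <- make_trials(c("A", "B", "A", "B", "A", "B"), c(1, 1, 1, 0, 1, 1),
                       rep("A", 6), rep("B", 6))
  s2 <- behavioral_summaries(shift, reward_probs = probs6)
  expect_equal(s2$win_stay, 0.0)
  expect_equal(s2$lose_shift, 1.0)
})

test_that("the six-trial hand fixture gives win-stay two thirds", {
  # rewarded at t1 (repeat), t2 (repeat), t4 (switch); t6 has no successor
  tr <- make_trials(c("A", "A", "A", "A", "B", "B"),
                    c(1, 1, 0, 1, 0, 1),
                    rep("A", 6), rep("B", 6))
  s <- behavioral_summaries(tr, reward_probs = probs6)
  expect_equal(s$win_stay, 2 / 3)
  expect_equal(s$n_win_stay, 3L)
})

test_that("an indifferent agent stays after wins about half the time", {
  design <- build_task_design(seed = 8)
  tr <- simulate_agent(design, agent_parameters(0.3, 0.3, 0), seed = 1)
  s <- behavioral_summaries(
    tr, reward_probs = setNames(design$symbols$reward_prob,
                                design$symbols$symbol))
  expect_lt(abs(s$win_stay - 0.5), 0.1)
  expect_lt(abs(s$lose_shift - 0.5), 0.1)
})

test_that("conditioning on the immediately preceding trial is available", {
  tr <- make_trials(c("A", "A", "C", "A"), c(1, 1, 1, 1),
                    c("A", "A", "C", "A"), c("B", "B", "D", "B"))
  pair_mode <- behavioral_summaries(tr, reward_probs = probs6)
  prev_mode <- behavioral_summaries(tr, reward_probs = probs6,
                                    condition = "previous_trial")
  expect_equal(pair_mode$n_win_stay, 2L) # t1 -> t2, t2 -> t4
  expect_equal(prev_mode$n_win_stay, 1L) # only t1 -> t2 is consecutive
})

test_that("missing trials and empty categories are handled", {
  tr <- make_trials(c("A", NA, "A"), c(1, NA, 1),
                    rep("A", 3), rep("B", 3))
  s <- behavioral_summaries(tr, reward_probs = probs6)
  expect_equal(s$n_training, 2L)
  expect_equal(s$n_lose_shift, 0L)
  expect_true(is.na(s$lose_shift))
})
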