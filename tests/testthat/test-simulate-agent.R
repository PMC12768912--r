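test_that("zero outcome sensitivity yields indifferent choice", {
  design <- build_task_design(seed = 3)
  trials <- simulate_agent(design, agent_parameters(0.3, 0.3, 0), seed = 1)
  train <- trials[trials$phase == "training", ]
  probs <- setNames(design$symbols$reward_prob, design$symbols$symbol)
  hi <- ifelse(probs[train$left_symbol] > probs[train$right_symbol],
               train$left_symbol, train$right_symbol)
  acc <- mean(train$chosen_symbol == hi)
  # 360 Bernoulli(0.5) draws: 4 sigma band
  expect_lt(abs(acc - 0.5), 4 * sqrt(0.25 / 360))
})

test_that("zero learning rates leave choices at chance for any beta", {
  design <- build_task_design(seed = 3)
  trials <- simulate_agent(design, agent_parameters(0, 0, 20), seed = 2)
  train <- trials[trials$phase == "training", ]
  probs <- setNames(design$symbols$reward_prob, design$symbols$symbol)
  hi <- ifelse(probs[train$left_symbol] > probs[train$right_symbol],
               train$left_symbol, train$right_symbol)
  expect_lt(abs(mean(train$chosen_symbol == hi) - 0.5), 4 * sqrt(0.25 / 360))
})

test_that("a sensitive learner masters the easy pair", {
  design <- build_task_design(seed = 4)
  probs <- setNames(design$symbols$reward_prob, design$symbols$symbol)
  accs <- vapply(1:60, function(s) {
    tr <- simulate_agent(design, agent_parameters(0.3, 0.3, 10), seed = s)
    tr <- tr[tr$phase == "training", ]
    pp <- pmax(probs[tr$left_symbol], probs[tr$right_symbol])
    easy <- tr[pp == 0.8, ]
    mean(easy$chosen_symbol ==
           ifelse(probs[easy$left_symbol] == 0.8, easy$left_symbol,
                  easy$right_symbol))
  }, numeric(1))
  expect_gt(mean(accs), 0.70)
})

test_that("simulation is deterministic and respects the trial schema", {
  design <- build_task_design(seed = 5, n_blocks = 1)
  t1 <- simulate_agent(design, agent_parameters(0.4, 0.2, 5), seed = 9)
  t2 <- simulate_agent(design, agent_parameters(0.4, 0.2, 5), seed = 9)
  expect_identical(t1, t2)
  expect_true(all(is.na(t1$outcome[t1$phase == "test"])))
  expect_true(all(t1$chosen_symbol == t1$left_symbol |
                    t1$chosen_symbol == t1$right_symbol))
})

test_that("missed trials are marked and excluded from outcomes", {
  design <- build_task_design(seed = 5, n_blocks = 1)
  tr <- simulate_agent(design, agent_parameters(0.4, 0.2, 5), seed = 9,
                       miss_rate = 0.3)
  miss <- is.na(tr$chosen_symbol)
  expect_gt(sum(miss), 10)
  expect_true(all(is.na(tr$outcome[miss])))
})

test_that("invalid parameters are rejected", {
  expect_error(agent_parameters(-0.1, 0.5, 1), "alpha_reward")
  expect_error(agent_parameters(0.5, 1.2, 1), "alpha_loss")
  expect_error(agent_parameters(0.5, 0.5, -2), "beta")
  design <- build_task_design(seed = 1, n_blocks = 1)
  expect_error(simulate_agent(design, agent_parameters(.2, .2, 1),
                              q_init = 1.5, seed = 1), "q_init")
})

test_that("Q-values stay in [0, 1] for 0/1 outcomes (replayed by oracle)", {
  design <- build_task_design(seed = 6, n_blocks = 1)
  for (s in 1:5) {
    aR <- runif(1); aL <- runif(1)
    tr <- simulate_agent(design, agent_parameters(aR, aL, 5), seed = s)
    tr <- tr[tr$phase == "training", ]
    Q <- setNames(rep(0.5, 6), LETTERS[1:6])
    for (t in seq_len(nrow(tr))) {
      ch <- tr$chosen_symbol[t]
      pe <- tr$outcome[t] - Q[[ch]]
      Q[[ch]] <- Q[[ch]] + (if (pe >= 0) aR else aL) * pe
      expect_true(all(Q >= 0 & Q <= 1))
    }
  }
})
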