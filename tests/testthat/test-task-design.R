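test_that("training schedule has the right structure", {
  design <- build_task_design(seed = 1)
  trials <- design$trials
  train <- trials[trials$phase == "training", ]
  expect_equal(nrow(train), 360)
  expect_equal(sum(trials$phase == "test"), 60)

  probs <- setNames(design$symbols$reward_prob, design$symbols$symbol)
  pair_probs <- paste(pmin(probs[train$left_symbol], probs[train$right_symbol]),
                      pmax(probs[train$left_symbol], probs[train$right_symbol]))
  # only the three fixed pairs, 120 presentations each
  expect_setequal(unique(pair_probs), c("0.2 0.8", "0.3 0.7", "0.4 0.6"))
  expect_true(all(table(pair_probs) == 120))
  # even split within every block, counterbalanced orientation
  per_block <- table(train$block, pair_probs)
  expect_true(all(per_block == 20))
  hi_left <- probs[train$left_symbol] > probs[train$right_symbol]
  expect_equal(sum(hi_left), 180)
})

test_that("test phase covers every pairing twice per left/right order", {
  design <- build_task_design(seed = 7)
  test <- design$trials[design$trials$phase == "test", ]
  ordered_pairs <- paste(test$left_symbol, test$right_symbol)
  expect_equal(length(unique(ordered_pairs)), 30) # 15 pairings x 2 orders
  expect_true(all(table(ordered_pairs) == 2))
})

test_that("symbol-probability assignment is a seeded permutation", {
  d1 <- build_task_design(seed = 1)
  d2 <- build_task_design(seed = 1)
  expect_identical(d1, d2)
  expect_setequal(d1$symbols$reward_prob, c(.2, .3, .4, .6, .7, .8))
  assignments <- vapply(1:20, function(s) {
    paste(build_task_design(seed = s)$symbols$reward_prob, collapse = ",")
  }, "")
  expect_gt(length(unique(assignments)), 1)
})

test_that("block and trial counts scale with the design arguments", {
  d <- build_task_design(seed = 2, n_blocks = 2)
  expect_equal(sum(d$trials$phase == "training"), 120)
  expect_error(build_task_design(seed = 1, trials_per_block = 50),
               "divisible")
})
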