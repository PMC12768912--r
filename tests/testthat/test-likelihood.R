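test_that("indifferent or symmetric choices have probability one half", {
  tr <- make_trials(c("A", "B", "A"), c(1, 0, 1),
                    c("A", "A", "A"), c("B", "B", "B"))
  expect_equal(trial_loglik(tr, agent_parameters(0.5, 0.1, 0)), 3 * log(0.5))
  one <- make_trials("A", 1, "A", "B")
  expect_equal(trial_loglik(one, agent_parameters(0.3, 0.3, 7)), log(0.5))
})

test_that("a hand-stepped three-trial sequence matches the recursion", {
  # aR = 0.5, aL = 0.1, beta = 2, q_init = 0.5, pair A/B throughout
  # t1: choose A (p = .5), win  -> Q_A = .75
  # t2: choose A (p = logistic(2 * .25)), lose -> Q_A = .675
  # t3: choose B (p = 1 - logistic(2 * .175))
  tr <- make_trials(c("A", "A", "B"), c(1, 0, 1),
                    c("A", "A", "A"), c("B", "B", "B"))
  manual <- log(0.5) + log(plogis(2 * 0.25)) + log(1 - plogis(2 * 0.175))
  expect_equal(trial_loglik(tr, agent_parameters(0.5, 0.1, 2)), manual,
               tolerance = 1e-12)
})

test_that("likelihood agrees with the explicit-loop oracle", {
  set.seed(101)
  for (i in 1:200) {
    cs <- random_loglik_case()
    for (variant in c("two_lr", "one_lr")) {
      got <- trial_loglik(cs$trials,
                          agent_parameters(cs$alpha_reward, cs$alpha_loss,
                                           cs$beta),
                          q_init = cs$q_init, variant = variant)
      want <- oracle_trial_loglik(cs$trials, cs$alpha_reward, cs$alpha_loss,
                                  cs$beta, cs$q_init, variant)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("missed trials are skipped with values carried forward", {
  full <- make_trials(c("A", "A", "B"), c(1, 0, 1),
                      c("A", "A", "A"), c("B", "B", "B"))
  with_miss <- make_trials(c("A", NA, "A", "B"), c(1, NA, 0, 1),
                           c("A", "A", "A", "A"), c("B", "B", "B", "B"))
  p <- agent_parameters(0.5, 0.1, 2)
  expect_equal(trial_loglik(with_miss, p), trial_loglik(full, p))
})

test_that("out-of-order or inconsistent trials are rejected", {
  tr <- make_trials(c("A", "B"), c(1, 0), c("A", "A"), c("B", "B"))
  bad <- tr[2:1, ]
  expect_error(trial_loglik(bad, agent_parameters(.3, .3, 1)),
               "presentation order")
  tr2 <- make_trials(c("C", "A"), c(1, 0), c("A", "A"), c("B", "B"))
  expect_error(trial_loglik(tr2, agent_parameters(.3, .3, 1)),
               "chosen_symbol")
})
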