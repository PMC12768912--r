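# one small cohort shared across the fitting tests
small_cohort <- generate_cohort(n_participants = 8, seed = 21, n_blocks = 2)

test_that("fits are bit-reproducible under a seed", {
  f1 <- fit_qlearning(small_cohort$trials, chains = 2, warmup = 150,
                      iter = 100, seed = 5, on_bad_fit = "ignore")
  f2 <- fit_qlearning(small_cohort$trials, chains = 2, warmup = 150,
                      iter = 100, seed = 5, on_bad_fit = "ignore")
  expect_identical(f1$params, f2$params)
  expect_identical(f1$group, f2$group)
})

test_that("draw bookkeeping and constraints hold for both variants", {
  for (variant in c("two_lr", "one_lr")) {
    fit <- fit_qlearning(small_cohort$trials, variant = variant, chains = 2,
                         warmup = 200, iter = 150, seed = 6,
                         target_accept = 0.9, on_bad_fit = "warn")
    n_par <- if (variant == "two_lr") 3L else 2L
    expect_length(fit$params, n_par)
    expect_equal(dim(fit$params[[1]]), c(300, 8))
    expect_true(all(fit$params[[1]] > 0 & fit$params[[1]] < 1))
    expect_true(all(fit$params$beta > 0))
    expect_equal(dim(fit$pointwise_loglik), c(300, 8))
    expect_true(all(fit$pointwise_loglik < 0))
    # pointwise log-lik matches direct evaluation at a frozen draw
    i <- 3; s <- 17
    pars <- lapply(fit$params, function(m) m[s, i])
    ll <- trial_loglik(
      small_cohort$trials[small_cohort$trials$participant_id ==
                            fit$participants[i], ],
      agent_parameters(pars[[1]], pars$alpha_loss %||% pars[[1]],
                       pars$beta),
      variant = variant)
    expect_equal(as.numeric(fit$pointwise_loglik[s, i]), ll,
                 tolerance = 1e-8)
  }
})

test_that("posterior means track generating parameters even in small fits", {
  fit <- fit_qlearning(small_cohort$trials, chains = 2, warmup = 250,
                       iter = 250, seed = 7, target_accept = 0.9,
                       on_bad_fit = "warn")
  est <- posterior_means(fit)
  truth <- small_cohort$ground_truth
  est <- est[match(truth$participant_id, est$participant_id), ]
  expect_gt(cor(est$alpha_reward, truth$alpha_reward), 0.4)
  expect_gt(cor(est$beta, truth$beta), 0.4)
})

test_that("diagnostics are reported for every fitted quantity", {
  fit <- fit_qlearning(small_cohort$trials, chains = 2, warmup = 200,
                       iter = 150, seed = 8, target_accept = 0.9,
                       on_bad_fit = "warn")
  g <- glance(fit)
  expect_true(all(c("divergences", "max_rhat", "min_ebfmi") %in% names(g)))
  # lp + (mu, sigma) per parameter + subject-level entries
  expect_equal(nrow(fit$diagnostics$rhat), 1 + 2 * 3 + 3 * 8)
  expect_true(all(is.finite(fit$diagnostics$rhat$rhat)))
  expect_length(fit$diagnostics$ebfmi, 2)
})

test_that("diagnostic breaches raise a typed error carrying the details", {
  # absurdly short warmup forces a detectable failure
  expect_error(
    suppressWarnings(fit_qlearning(small_cohort$trials, chains = 2,
                                   warmup = 8, iter = 40, seed = 1)),
    class = "glycolearn_diagnostic_error")
})

test_that("a single participant still fits, with a warning", {
  one <- small_cohort$trials[small_cohort$trials$participant_id == "P01", ]
  expect_warning(
    fit <- fit_qlearning(one, chains = 2, warmup = 200, iter = 100, seed = 2,
                         target_accept = 0.95, on_bad_fit = "ignore"),
    "< 2 participants")
  expect_equal(length(fit$participants), 1)
})

test_that("participant order does not change posterior summaries", {
  ids <- unique(small_cohort$trials$participant_id)
  permuted <- small_cohort$trials |>
    dplyr::arrange(match(participant_id, rev(ids)), trial)
  f1 <- fit_qlearning(small_cohort$trials, chains = 2, warmup = 200,
                      iter = 150, seed = 11, target_accept = 0.9,
                      on_bad_fit = "ignore")
  f2 <- fit_qlearning(permuted, chains = 2, warmup = 200, iter = 150,
                      seed = 11, target_accept = 0.9, on_bad_fit = "ignore")
  m1 <- posterior_means(f1)
  m2 <- posterior_means(f2)
  m2 <- m2[match(m1$participant_id, m2$participant_id), ]
  # same data content, different ordering: equal up to MCMC noise
  expect_lt(max(abs(m1$alpha_reward - m2$alpha_reward)), 0.08)
  expect_lt(max(abs(log(m1$beta) - log(m2$beta))), 0.3)
})

test_that("tidy output is one row per participant and parameter", {
  fit <- fit_qlearning(small_cohort$trials, chains = 2, warmup = 150,
                       iter = 100, seed = 9, on_bad_fit = "ignore")
  td <- tidy(fit)
  expect_equal(nrow(td), 3 * 8)
  expect_true(all(td$hdi90_lower <= td$estimate &
                    td$estimate <= td$hdi90_upper))
})
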