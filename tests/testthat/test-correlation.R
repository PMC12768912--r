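# build a minimal ql_fit-shaped object from raw draws matrices
fake_fit <- function(alpha_draws, ids = colnames(alpha_draws)) {
  structure(list(
    params = list(alpha_reward = alpha_draws,
                  beta = alpha_draws * 0 + 1),
    unconstrained = list(alpha_reward = qlogis(alpha_draws),
                         beta = alpha_draws * 0),
    participants = ids
  ), class = "ql_fit")
}

test_that("a covariate equal to one frozen draw correlates perfectly there", {
  set.seed(1)
  m <- matrix(runif(10 * 8, 0.1, 0.9), 10, 8,
              dimnames = list(NULL, paste0("P", 1:8)))
  fit <- fake_fit(m)
  cp <- posterior_correlation(fit, "alpha_reward",
                              setNames(m[4, ], colnames(m)))
  expect_equal(cp$draws[4], 1)
  expect_true(all(cp$draws >= -1 & cp$draws <= 1))
})

test_that("constant draws reduce to the ordinary Pearson correlation", {
  set.seed(2)
  vals <- runif(8, 0.2, 0.8)
  m <- matrix(rep(vals, each = 50), 50, 8,
              dimnames = list(NULL, paste0("P", 1:8)))
  covariate <- rnorm(8)
  names(covariate) <- colnames(m)
  cp <- posterior_correlation(fake_fit(m), "alpha_reward", covariate)
  expect_equal(cp$mean, cor(vals, covariate), tolerance = 1e-12)
  expect_equal(cp$hdi90$lower, cp$hdi90$upper)
})

test_that("summaries nest and validate", {
  set.seed(3)
  m <- matrix(runif(4000 * 8), 4000, 8,
              dimnames = list(NULL, paste0("P", 1:8)))
  fit <- fake_fit(m)
  covariate <- setNames(rnorm(8), colnames(m))
  cp <- posterior_correlation(fit, "alpha_reward", covariate)
  expect_gte(cp$hdi66$lower, cp$hdi90$lower)
  expect_lte(cp$hdi66$upper, cp$hdi90$upper)
  expect_true(cp$p_positive >= 0 && cp$p_positive <= 1)
  expect_error(posterior_correlation(fit, "nope", covariate), "not in fit")
  expect_error(posterior_correlation(fit, "alpha_reward",
                                     setNames(rep(1, 8), colnames(m))),
               "zero variance")
  expect_error(posterior_correlation(fit, "alpha_reward", rnorm(5)),
               "one value per")
})

test_that("with no true association P(r > 0) is spread around one half", {
  set.seed(4)
  p_pos <- vapply(1:40, function(i) {
    m <- matrix(plogis(rnorm(200) + rep(rnorm(10), each = 200)), 200, 10,
                dimnames = list(NULL, paste0("P", 1:10)))
    covariate <- setNames(rnorm(10), colnames(m))
    posterior_correlation(fake_fit(m), "alpha_reward", covariate)$p_positive
  }, numeric(1))
  # approximately uniform over replications: centred, dispersed, two-sided
  expect_gt(mean(p_pos), 0.3)
  expect_lt(mean(p_pos), 0.7)
  expect_gt(sd(p_pos), 0.15)
  expect_gt(sum(p_pos > 0.5), 5)
  expect_gt(sum(p_pos < 0.5), 5)
})
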