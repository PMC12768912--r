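test_that("a strong linear signal is recovered with a decisive HDI", {
  d <- tibble::tibble(x = seq(-2, 2, length.out = 100))
  d$y <- 2 * d$x
  fit <- bayesian_regression(d, y ~ x, seed = 1)
  co <- tidy(fit)
  slope <- co[co$term == "x", ]
  expect_equal(slope$estimate, 2, tolerance = 0.05)
  expect_true(slope$excludes_zero_90)
  expect_lt(max(co$rhat, na.rm = TRUE), 1.1)
})

test_that("an intercept-only model recovers the sample mean", {
  set.seed(2)
  d <- tibble::tibble(y = rnorm(50, 10, 2))
  fit <- bayesian_regression(d, y ~ 1, seed = 3)
  expect_equal(tidy(fit)$estimate[1], mean(d$y), tolerance = 0.2)
})

test_that("pure-noise slopes overlap zero at roughly the nominal rate", {
  overlaps <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    d <- tibble::tibble(x = rnorm(30), y = rnorm(30))
    co <- tidy(bayesian_regression(d, y ~ x, seed = s))
    !co$excludes_zero_90[co$term == "x"]
  }, logical(1))
  expect_gte(mean(overlaps), 0.7)
})

test_that("degenerate designs are rejected", {
  d <- tibble::tibble(x = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(bayesian_regression(d, y ~ x + x2, seed = 1),
               "rank deficient")
  expect_error(bayesian_regression(d[1:2, ], y ~ x, seed = 1), "at least 3")
})

test_that("draws are reproducible under a seed", {
  d <- tibble::tibble(x = 1:20, y = (1:20) + c(0.5, -0.5))
  f1 <- bayesian_regression(d, y ~ x, seed = 7)
  f2 <- bayesian_regression(d, y ~ x, seed = 7)
  expect_identical(f1$draws, f2$draws)
})
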