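#' Bayesian linear regression with HDI reporting
#'
#' Normal-likelihood linear regression sampled by a Gibbs sampler under
#' weakly-informative priors, for exploratory covariate analyses (e.g.
#' glucose metrics against age or questionnaire scores). Priors follow the
#' usual autoscaling convention: intercept N(mean(y), (10 sd(y))^2), slopes
#' N(0, (2.5 sd(y) / sd(x_j))^2), and an inverse-gamma prior on the residual
#' variance. Coefficients and the residual variance have conjugate full
#' conditionals, so the chain mixes essentially immediately; four chains are
#' still run and split-Rhat reported.
#'
#' @param data A data frame of complete cases (rows with missing values in
#'   the model variables are dropped; >= 3 rows must remain).
#' @param formula Model formula, e.g. `iauc ~ age`.
#' @param seed Integer seed.
#' @param chains,warmup,iter Sampler settings (defaults 4, 200, 1000 for
#'   4000 retained draws).
#' @return An object of class `bayes_lm`: `draws` (tibble of coefficient and
#'   sigma draws), `coef` summary tibble with posterior means, 90% and 66%
#'   HDIs and whether each excludes zero, plus metadata. `tidy()` returns
#'   the summary.
#' @export
#' @examples
#' d <- tibble::tibble(x = 1:20, y = 2 * x + rnorm(20))
#' fit <- bayesian_regression(d, y ~ x, seed = 1)
#' tidy(fit)
bayesian_regression <- function(data, formula, seed, chains = 4,
                                warmup = 200, iter = 1000) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  assert_that(n >= 3, "need at least 3 complete cases")
  if (qr(X)$rank < ncol(X)) rlang::abort("design matrix is rank deficient")
  p <- ncol(X)

  sy <- stats::sd(y)
  if (sy == 0) sy <- 1
  prior_mean <- c(mean(y), rep(0, p - 1))[seq_len(p)]
  prior_sd <- vapply(seq_len(p), function(j) {
    if (colnames(X)[j] == "(Intercept)") return(10 * sy)
    sx <- stats::sd(X[, j])
    if (sx == 0) sx <- 1
    2.5 * sy / sx
  }, numeric(1))
  a0 <- 2; b0 <- sy^2 # inverse-gamma prior on sigma^2

  withr_seed(fanout_seed(seed, "bayes-lm"))
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  V0inv <- diag(1 / prior_sd^2, p)
  V0m0 <- prior_mean / prior_sd^2

  total <- chains * iter
  out <- matrix(NA_real_, total, p + 1)
  chain_lab <- integer(total)
  row <- 0L
  for (c in seq_len(chains)) {
    sigma2 <- stats::var(y)
    beta <- rep(0, p)
    for (it in seq_len(warmup + iter)) {
      Vn <- chol2inv(chol(XtX / sigma2 + V0inv))
      mn <- Vn %*% (Xty / sigma2 + V0m0)
      beta <- as.numeric(mn + t(chol(Vn)) %*% stats::rnorm(p))
      resid <- y - X %*% beta
      sigma2 <- 1 / stats::rgamma(1, a0 + n / 2,
                                  b0 + sum(resid^2) / 2)
      if (it > warmup) {
        row <- row + 1L
        out[row, ] <- c(beta, sqrt(sigma2))
        chain_lab[row] <- c
      }
    }
  }
  colnames(out) <- c(colnames(X), "sigma")
  draws <- tibble::as_tibble(as.data.frame(out))
  draws$chain <- chain_lab

  coef_tbl <- purrr::map_dfr(colnames(X), function(nm) {
    x <- out[, nm]
    h90 <- hdi(x, 0.90); h66 <- hdi(x, 0.66)
    tibble::tibble(
      term = nm, estimate = mean(x),
      hdi90_lower = h90$lower, hdi90_upper = h90$upper,
      hdi66_lower = h66$lower, hdi66_upper = h66$upper,
      excludes_zero_90 = h90$lower > 0 | h90$upper < 0,
      excludes_zero_66 = h66$lower > 0 | h66$upper < 0,
      rhat = split_rhat(x, chains)
    )
  })

  structure(
    list(draws = draws, coef = coef_tbl, formula = formula, n = n,
         chains = chains, iter = iter, seed = seed),
    class = "bayes_lm"
  )
}

#' @export
print.bayes_lm <- function(x, ...) {
  cat("<bayes_lm>", deparse(x$formula), " n =", x$n, "\n")
  print(x$coef[, c("term", "estimate", "hdi90_lower", "hdi90_upper")])
  invisible(x)
}
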