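#' Trend in momentary affect ratings
#'
#' Hierarchical (mixed-effects) Bayesian linear model of affect ratings on
#' trial number: rating ~ intercept + slope * (trial - 1) with correlated-
#' free random intercepts and random slopes per participant, Gaussian noise,
#' fitted by a Gibbs sampler (all full conditionals are conjugate). The
#' fixed intercept is the expected rating on trial 1 and the fixed slope is
#' the change in percentage points per trial. An optional per-participant
#' moderator adds main-effect and moderator-by-trial interaction terms
#' (e.g. to ask whether higher reward learning rates slow the decline in
#' engagement).
#'
#' Random-effect variances get inverse-gamma priors scaled to the spread of
#' per-participant least-squares estimates; fixed effects get flat-ish
#' normal priors.
#'
#' @param trials Tibble of trial records with `affect_type` and
#'   `affect_rating` columns.
#' @param type Which rating stream to model (e.g. `"happiness"`).
#' @param seed Integer seed.
#' @param moderator Optional named per-participant numeric vector; adds
#'   `moderator` and `trial:moderator` fixed effects (moderator is
#'   standardised internally).
#' @param chains,warmup,iter Sampler settings (defaults 4, 200, 1000).
#' @return An object of class `affect_trend`: `fixed` summary tibble
#'   (posterior mean, 90% / 66% HDIs per fixed effect), `draws`, random-
#'   effect SD summaries, and metadata.
#' @export
affect_trend <- function(trials, type, seed, moderator = NULL, chains = 4,
                         warmup = 200, iter = 1000) {
  d <- trials[!is.na(trials$affect_rating) & trials$affect_type == type &
                trials$phase == "training", ]
  if (nrow(d) == 0) rlang::abort(paste("no ratings of type", type))
  ids <- unique(d$participant_id)
  counts <- table(d$participant_id)
  assert_that(length(ids) >= 2 && all(counts >= 2),
              "need >= 2 participants with >= 2 ratings each")

  y <- d$affect_rating
  t0 <- d$trial - 1
  g <- match(d$participant_id, ids)
  J <- length(ids)
  n <- length(y)

  X <- cbind(`(Intercept)` = 1, trial = t0)
  if (!is.null(moderator)) {
    m <- align_covariate(moderator, ids)
    m <- as.numeric(scale(m))
    X <- cbind(X, moderator = m[g], `trial:moderator` = t0 * m[g])
  }
  p <- ncol(X)

  # per-participant OLS fits set the scale of the random-effect priors
  ols <- t(vapply(seq_len(J), function(j) {
    idx <- g == j
    stats::coef(stats::lm(y[idx] ~ t0[idx]))
  }, numeric(2)))
  tau_scale <- pmax(apply(ols, 2, stats::sd, na.rm = TRUE), 1e-3)

  sy <- stats::sd(y)
  prior_sd_fixed <- c(10 * sy, rep(2.5 * sy / max(stats::sd(t0), 1), p - 1))
  prior_sd_fixed[1] <- 10 * max(sy, 1)

  withr_seed(fanout_seed(seed, "affect-trend"))
  V0inv <- diag(1 / prior_sd_fixed^2, p)
  XtX <- crossprod(X)
  # per-participant design blocks are fixed across iterations
  blocks <- lapply(seq_len(J), function(j) {
    idx <- which(g == j)
    W <- cbind(1, t0[idx])
    list(idx = idx, W = W, WtW = crossprod(W))
  })

  total <- chains * iter
  fixed_draws <- matrix(NA_real_, total, p)
  var_draws <- matrix(NA_real_, total, 3) # tau0, tau1, sigma
  chain_lab <- integer(total)
  row <- 0L

  for (c in seq_len(chains)) {
    beta <- rep(0, p); beta[1] <- mean(y)
    u <- matrix(0, J, 2)
    tau2 <- tau_scale^2 + 1e-6
    sigma2 <- sy^2

    for (it in seq_len(warmup + iter)) {
      # fixed effects | random effects, sigma2
      ystar <- y - u[g, 1] - u[g, 2] * t0
      Vn <- chol2inv(chol(XtX / sigma2 + V0inv))
      mn <- Vn %*% (crossprod(X, ystar) / sigma2)
      beta <- as.numeric(mn + t(chol(Vn)) %*% stats::rnorm(p))

      # random effects per participant (2x2 conjugate normal)
      resid_fixed <- y - X %*% beta
      for (j in seq_len(J)) {
        bl <- blocks[[j]]
        prec <- bl$WtW / sigma2 + diag(1 / tau2, 2)
        Vj <- chol2inv(chol(prec))
        mj <- Vj %*% (crossprod(bl$W, resid_fixed[bl$idx]) / sigma2)
        u[j, ] <- as.numeric(mj + t(chol(Vj)) %*% stats::rnorm(2))
      }

      # variance components
      tau2[1] <- 1 / stats::rgamma(1, 1 + J / 2,
                                   tau_scale[1]^2 + sum(u[, 1]^2) / 2)
      tau2[2] <- 1 / stats::rgamma(1, 1 + J / 2,
                                   tau_scale[2]^2 + sum(u[, 2]^2) / 2)
      resid <- resid_fixed - u[g, 1] - u[g, 2] * t0
      sigma2 <- 1 / stats::rgamma(1, 2 + n / 2, sy^2 + sum(resid^2) / 2)

      if (it > warmup) {
        row <- row + 1L
        fixed_draws[row, ] <- beta
        var_draws[row, ] <- c(sqrt(tau2), sqrt(sigma2))
        chain_lab[row] <- c
      }
    }
  }
  colnames(fixed_draws) <- colnames(X)
  colnames(var_draws) <- c("sd_intercept", "sd_slope", "sigma")

  fixed <- purrr::map_dfr(colnames(X), function(nm) {
    x <- fixed_draws[, nm]
    h90 <- hdi(x, 0.90); h66 <- hdi(x, 0.66)
    tibble::tibble(term = nm, estimate = mean(x),
                   hdi90_lower = h90$lower, hdi90_upper = h90$upper,
                   hdi66_lower = h66$lower, hdi66_upper = h66$upper,
                   rhat = split_rhat(x, chains))
  })

  structure(
    list(fixed = fixed,
         draws = tibble::as_tibble(as.data.frame(
           cbind(fixed_draws, var_draws, chain = chain_lab))),
         type = type, n_participants = J, n_ratings = n,
         chains = chains, iter = iter, seed = seed),
    class = "affect_trend"
  )
}

#' @export
print.affect_trend <- function(x, ...) {
  est <- x$fixed
  cat(sprintf(
    "<affect_trend> %s: start %.1f%%, slope %+.3f points/trial (90%% HDI [%.3f, %.3f])\n",
    x$type, est$estimate[est$term == "(Intercept)"],
    est$estimate[est$term == "trial"],
    est$hdi90_lower[est$term == "trial"],
    est$hdi90_upper[est$term == "trial"]))
  invisible(x)
}
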