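# Independent reference implementations used as oracles. These deliberately
# share no code with the package: explicit loops, brute-force scans and
# fine-grid numeric integration.

# explicit-loop Q-learning log-likelihood (no vectorisation, no C++)
oracle_trial_loglik <- function(trials, alpha_reward, alpha_loss, beta,
                                q_init = 0.5, variant = "two_lr") {
  tr <- trials[trials$phase == "training", ]
  symbols <- sort(unique(c(trials$left_symbol, trials$right_symbol)))
  Q <- rep(q_init, length(symbols))
  names(Q) <- symbols
  ll <- 0
  for (t in seq_len(nrow(tr))) {
    ch <- tr$chosen_symbol[t]
    if (is.na(ch) || is.na(tr$outcome[t])) next
    other <- if (ch == tr$left_symbol[t]) tr$right_symbol[t] else tr$left_symbol[t]
    p <- 1 / (1 + exp(-beta * (Q[[ch]] - Q[[other]])))
    ll <- ll + log(p)
    pe <- tr$outcome[t] - Q[[ch]]
    a <- if (variant == "one_lr") alpha_reward else {
      if (pe >= 0) alpha_reward else alpha_loss
    }
    Q[[ch]] <- Q[[ch]] + a * pe
  }
  ll
}

# brute-force shortest interval containing >= ceiling(mass * n) samples
oracle_hdi <- function(samples, mass = 0.9) {
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    j <- i + k - 1
    if (j > n) break
    if ((x[j] - x[i]) < (best[2] - best[1])) best <- c(x[i], x[j])
  }
  best
}

# numeric integration of max(piecewise-linear curve - baseline, 0): each
# segment is split at its baseline crossing (located by root finding on the
# interpolant) so the quadrature only ever sees smooth pieces
oracle_iauc_numeric <- function(t, y, baseline, ...) {
  excess <- function(tt) approx(t, y, xout = tt)$y - baseline
  pos <- function(tt) pmax(excess(tt), 0)
  total <- 0
  for (k in seq_len(length(t) - 1)) {
    a <- t[k]; b <- t[k + 1]
    knots <- c(a, b)
    if (excess(a) * excess(b) < 0) {
      knots <- c(a, uniroot(excess, c(a, b), tol = 1e-14)$root, b)
    }
    for (j in seq_len(length(knots) - 1)) {
      total <- total + integrate(pos, knots[j], knots[j + 1],
                                 rel.tol = 1e-12, abs.tol = 1e-14,
                                 subdivisions = 200L)$value
    }
  }
  total
}

# build a bare trial-record tibble by hand
make_trials <- function(chosen, outcome, left, right, phase = "training",
                        id = "P1") {
  tibble::tibble(
    participant_id = id, phase = phase,
    block = ifelse(phase == "training", 1L, NA_integer_),
    trial = seq_along(chosen), left_symbol = left, right_symbol = right,
    chosen_symbol = chosen, outcome = outcome,
    affect_type = NA_character_, affect_rating = NA_real_
  )
}

# random short trial sequence + parameters for likelihood property tests
random_loglik_case <- function() {
  n <- sample(5:25, 1)
  symbols <- LETTERS[1:6]
  left <- sample(symbols, n, replace = TRUE)
  right <- vapply(left, function(l) sample(setdiff(symbols, l), 1), "")
  pickL <- runif(n) < 0.5
  chosen <- ifelse(pickL, left, right)
  list(
    trials = make_trials(chosen, rbinom(n, 1, 0.5), left, right),
    alpha_reward = runif(1), alpha_loss = runif(1),
    beta = runif(1, 0, 10), q_init = runif(1)
  )
}
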