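#' Agent parameters for the Q-learning model
#'
#' Bundles and validates the three subject-level parameters of the
#' dual-learning-rate Rescorla-Wagner model: the reward learning rate
#' (applied to positive prediction errors), the loss learning rate (negative
#' prediction errors) and the outcome sensitivity / inverse temperature that
#' scales value differences in the logistic choice rule.
#'
#' @param alpha_reward Learning rate for positive prediction errors, in
#'   \[0, 1\].
#' @param alpha_loss Learning rate for negative prediction errors, in
#'   \[0, 1\]. Defaults to `alpha_reward` (single-learning-rate agent).
#' @param beta Outcome sensitivity (inverse temperature), non-negative.
#' @return A list of class `agent_parameters`.
#' @export
#' @examples
#' agent_parameters(alpha_reward = 0.4, alpha_loss = 0.2, beta = 5)
agent_parameters <- function(alpha_reward, alpha_loss = alpha_reward, beta) {
  ok <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
  if (!ok(alpha_reward) || alpha_reward < 0 || alpha_reward > 1)
    rlang::abort("alpha_reward must be a single value in [0, 1]")
  if (!ok(alpha_loss) || alpha_loss < 0 || alpha_loss > 1)
    rlang::abort("alpha_loss must be a single value in [0, 1]")
  if (!ok(beta) || beta < 0)
    rlang::abort("beta must be a single non-negative value")
  structure(list(alpha_reward = alpha_reward, alpha_loss = alpha_loss,
                 beta = beta),
            class = "agent_parameters")
}

#' Simulate an agent performing the probabilistic selection task
#'
#' Plays a `task_design` with a softmax Q-learning agent. On every trial the
#' probability of choosing the left symbol is
#' `plogis(beta * (Q_left - Q_right))`; after a training choice the chosen
#' symbol's value is updated by `Q <- Q + alpha * (R - Q)` with
#' `alpha_reward` when the prediction error is positive (ties included) and
#' `alpha_loss` when negative. Outcomes are Bernoulli draws with the chosen
#' symbol's reward probability. Test-phase choices use the final training
#' Q-values with no outcome and no updating. Optionally, trials are missed at
#' a fixed rate, in which case the choice is recorded as `NA` and Q-values
#' carry forward unchanged.
#'
#' @param design A `task_design`.
#' @param params An `agent_parameters` object (or list with the same fields).
#' @param q_init Initial Q-value for every symbol, in \[0, 1\] (default 0.5,
#'   the midpoint of the 0/1 outcome scale).
#' @param seed Integer seed.
#' @param participant_id Identifier stored in the output (default `"sim"`).
#' @param miss_rate Probability that a trial is missed (default 0).
#' @param affect Optional tibble of affect ratings to attach, as produced by
#'   [simulate_affect_trajectory()]; one row per training trial with columns
#'   `affect_type` and `affect_rating`.
#' @return A tibble of trial records: `participant_id`, `phase`, `block`,
#'   `trial`, `left_symbol`, `right_symbol`, `chosen_symbol`, `outcome`,
#'   `affect_type`, `affect_rating`.
#' @export
#' @examples
#' design <- build_task_design(seed = 1)
#' trials <- simulate_agent(design, agent_parameters(0.4, 0.2, 5), seed = 2)
#' head(trials)
simulate_agent <- function(design, params, q_init = 0.5, seed,
                           participant_id = "sim", miss_rate = 0,
                           affect = NULL) {
  stopifnot(inherits(design, "task_design"))
  params <- agent_parameters(params$alpha_reward,
                             params$alpha_loss %||% params$alpha_reward,
                             params$beta)
  if (!is.numeric(q_init) || q_init < 0 || q_init > 1)
    rlang::abort("q_init must be in [0, 1]")
  withr_seed(seed)

  symbols <- design$symbols$symbol
  probs <- stats::setNames(design$symbols$reward_prob, symbols)
  Q <- stats::setNames(rep(q_init, length(symbols)), symbols)

  tr <- design$trials
  n <- nrow(tr)
  chosen <- character(n)
  outcome <- rep(NA_real_, n)
  miss <- if (miss_rate > 0) stats::runif(n) < miss_rate else rep(FALSE, n)

  for (t in seq_len(n)) {
    if (miss[t]) {
      chosen[t] <- NA_character_
      next
    }
    l <- tr$left_symbol[t]; r <- tr$right_symbol[t]
    p_left <- stats::plogis(params$beta * (Q[[l]] - Q[[r]]))
    ch <- if (stats::runif(1) < p_left) l else r
    chosen[t] <- ch
    if (tr$phase[t] == "training") {
      R <- stats::rbinom(1, 1, probs[[ch]])
      outcome[t] <- R
      pe <- R - Q[[ch]]
      a <- if (pe >= 0) params$alpha_reward else params$alpha_loss
      Q[[ch]] <- Q[[ch]] + a * pe
    }
  }

  out <- dplyr::mutate(tr,
    participant_id = participant_id,
    chosen_symbol = chosen,
    outcome = outcome,
    .before = 1
  )
  out <- dplyr::relocate(out, "participant_id", "phase", "block", "trial")

  if (!is.null(affect)) {
    n_train <- sum(out$phase == "training")
    assert_that(nrow(affect) == n_train,
                "affect must have one row per training trial")
    out$affect_type <- c(affect$affect_type, rep(NA_character_,
                                                 n - n_train))
    out$affect_rating <- c(affect$affect_rating, rep(NA_real_, n - n_train))
  } else {
    out$affect_type <- NA_character_
    out$affect_rating <- NA_real_
  }
  out
}
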