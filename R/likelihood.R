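#' Log-likelihood of one participant's training choices
#'
#' Evaluates the Q-learning model likelihood by forward recursion over one
#' participant's training trials in presentation order. Each recorded choice
#' contributes the log of its logistic choice probability
#' `plogis(beta * (Q_chosen - Q_unchosen))`; the chosen symbol's Q-value is
#' then updated with the recorded outcome via the Rescorla-Wagner rule,
#' using `alpha_reward` for non-negative prediction errors and `alpha_loss`
#' for negative ones (a single rate model uses `alpha_reward` throughout).
#' Missed trials (`chosen_symbol` `NA`) are skipped with Q-values carried
#' forward unchanged.
#'
#' @param trials Tibble of one participant's trial records (training phase
#'   rows are used), ordered by `trial`.
#' @param params An [agent_parameters()] object or equivalent list.
#' @param q_init Initial Q-value (default 0.5).
#' @param variant `"two_lr"` or `"one_lr"`.
#' @return The summed log-likelihood (scalar).
#' @export
#' @examples
#' design <- build_task_design(seed = 1, n_blocks = 1)
#' trials <- simulate_agent(design, agent_parameters(0.4, 0.2, 5), seed = 2)
#' trial_loglik(trials, agent_parameters(0.4, 0.2, 5))
trial_loglik <- function(trials, params, q_init = 0.5,
                         variant = c("two_lr", "one_lr")) {
  variant <- match.arg(variant)
  params <- agent_parameters(params$alpha_reward,
                             params$alpha_loss %||% params$alpha_reward,
                             params$beta)
  prep <- prepare_likelihood_data(trials)
  if (prep$n_trials == 0) return(0)
  aL <- if (variant == "one_lr") params$alpha_reward else params$alpha_loss
  rl_trial_loglik_cpp(params$alpha_reward, aL, params$beta, prep$chosen,
                      prep$other, prep$reward, length(prep$symbols), q_init)
}

# shared validation/encoding for likelihood evaluation and model fitting;
# returns 1-based symbol indices of chosen/unchosen per valid training trial
prepare_likelihood_data <- function(trials, symbols = NULL) {
  assert_that(is.data.frame(trials), "trials must be a data frame")
  req <- c("phase", "trial", "left_symbol", "right_symbol", "chosen_symbol",
           "outcome")
  assert_that(all(req %in% names(trials)),
              paste("trials must have columns:", paste(req, collapse = ", ")))
  tr <- trials[trials$phase == "training", ]
  if (is.unsorted(tr$trial, strictly = TRUE)) {
    rlang::abort("training trials must be in presentation order")
  }
  tr <- tr[!is.na(tr$chosen_symbol) & !is.na(tr$outcome), ]
  symbols <- symbols %||%
    sort(unique(c(trials$left_symbol, trials$right_symbol)))
  chosen <- match(tr$chosen_symbol, symbols)
  left <- match(tr$left_symbol, symbols)
  right <- match(tr$right_symbol, symbols)
  bad <- is.na(chosen) | (chosen != left & chosen != right)
  assert_that(!any(bad),
              "chosen_symbol must be one of left_symbol/right_symbol")
  other <- ifelse(chosen == left, right, left)
  list(chosen = as.integer(chosen), other = as.integer(other),
       reward = as.numeric(tr$outcome), symbols = symbols,
       n_trials = nrow(tr))
}
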