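#' Model-agnostic behavioural summaries
#'
#' Per-participant accuracy and win-stay/lose-shift statistics. Accuracy is
#' the probability of choosing the symbol with the higher reward probability,
#' separately for the training and test phases. Win-stay is the probability
#' of repeating the previously chosen symbol on the next presentation of the
#' same stimulus pair given that the previous choice of that pair was
#' rewarded; lose-shift is the probability of switching after a non-reward.
#' Because pairs interleave, conditioning is on the next presentation of the
#' same unordered pair by default; `condition = "previous_trial"` instead
#' conditions on the immediately preceding trial (counting only consecutive
#' trials that show the same pair). Missed trials are excluded from
#' numerators and denominators; empty categories yield `NA` rates with zero
#' counts.
#'
#' @param trials Tibble of trial records for one or more participants. Reward
#'   probabilities are taken from `reward_probs` when supplied, otherwise
#'   inferred from observed training outcome rates per symbol.
#' @param reward_probs Optional named vector of reward probabilities per
#'   symbol (names = symbols).
#' @param condition `"pair"` (default) or `"previous_trial"`.
#' @return A tibble with one row per participant: `participant_id`,
#'   `training_accuracy`, `test_accuracy`, `win_stay`, `lose_shift` and the
#'   contributing counts.
#' @export
#' @examples
#' design <- build_task_design(seed = 1, n_blocks = 1)
#' trials <- simulate_agent(design, agent_parameters(0.5, 0.3, 8), seed = 2)
#' behavioral_summaries(trials,
#'   reward_probs = setNames(design$symbols$reward_prob,
#'                           design$symbols$symbol))
behavioral_summaries <- function(trials, reward_probs = NULL,
                                 condition = c("pair", "previous_trial")) {
  condition <- match.arg(condition)
  if (is.null(reward_probs)) {
    tr <- trials[trials$phase == "training" & !is.na(trials$outcome), ]
    reward_probs <- tapply(tr$outcome, tr$chosen_symbol, mean)
  }
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ one_behavioral_summary(.x, reward_probs,
                                                 condition)) |>
    dplyr::ungroup()
}

one_behavioral_summary <- function(trials, probs, condition) {
  ok <- !is.na(trials$chosen_symbol)
  p_l <- probs[trials$left_symbol]
  p_r <- probs[trials$right_symbol]
  hi <- ifelse(p_l >= p_r, trials$left_symbol, trials$right_symbol)
  correct <- trials$chosen_symbol == hi

  tr_idx <- ok & trials$phase == "training"
  te_idx <- ok & trials$phase == "test"

  train <- trials[trials$phase == "training" & ok, ]
  pair_key <- paste(pmin(train$left_symbol, train$right_symbol),
                    pmax(train$left_symbol, train$right_symbol))
  ws_num <- ws_den <- ls_num <- ls_den <- 0L
  n <- nrow(train)
  for (t in seq_len(n)) {
    if (is.na(train$outcome[t])) next
    nxt <- if (condition == "pair") {
      later <- which(pair_key == pair_key[t])
      later <- later[later > t]
      if (length(later)) later[1] else NA_integer_
    } else {
      if (t < n && pair_key[t + 1] == pair_key[t]) t + 1L else NA_integer_
    }
    if (is.na(nxt)) next
    stayed <- train$chosen_symbol[nxt] == train$chosen_symbol[t]
    if (train$outcome[t] == 1) {
      ws_den <- ws_den + 1L
      ws_num <- ws_num + as.integer(stayed)
    } else {
      ls_den <- ls_den + 1L
      ls_num <- ls_num + as.integer(!stayed)
    }
  }

  tibble::tibble(
    training_accuracy = if (any(tr_idx)) mean(correct[tr_idx]) else NA_real_,
    test_accuracy = if (any(te_idx)) mean(correct[te_idx]) else NA_real_,
    win_stay = if (ws_den > 0) ws_num / ws_den else NA_real_,
    lose_shift = if (ls_den > 0) ls_num / ls_den else NA_real_,
    n_training = sum(tr_idx), n_test = sum(te_idx),
    n_win_stay = ws_den, n_lose_shift = ls_den
  )
}
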