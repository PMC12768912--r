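#' Posterior-predictive choice accuracies
#'
#' Simulates agents from a subsample of posterior draws playing a task
#' design, returning the distribution of per-pair accuracy (probability of
#' choosing the higher-probability symbol) in each phase. Used to overlay
#' model predictions against empirical accuracies.
#'
#' @param fit A `ql_fit`.
#' @param design A `task_design` to replay (each sampled draw simulates all
#'   fitted participants on this design).
#' @param n_draws Number of posterior draws to simulate (default 50).
#' @param seed Integer seed.
#' @return A tibble with `rep`, `phase`, `pair` (e.g. `"80-20"`) and
#'   `accuracy`, one row per simulated draw and pair.
#' @export
posterior_predict_accuracy <- function(fit, design, n_draws = 50, seed) {
  stopifnot(inherits(fit, "ql_fit"), inherits(design, "task_design"))
  if (n_draws < 1) rlang::abort("n_draws must be at least 1")
  S <- nrow(fit$params[[1]])
  withr_seed(fanout_seed(seed, "ppc-pick"))
  take <- sample(S, min(n_draws, S))
  two_lr <- fit$variant == "two_lr"
  purrr::map_dfr(seq_along(take), function(k) {
    s <- take[k]
    sims <- purrr::map_dfr(seq_along(fit$participants), function(i) {
      aR <- fit$params[[if (two_lr) "alpha_reward" else "alpha"]][s, i]
      aL <- if (two_lr) fit$params$alpha_loss[s, i] else aR
      bb <- fit$params$beta[s, i]
      simulate_agent(design, agent_parameters(aR, aL, bb),
                     q_init = fit$q_init,
                     seed = fanout_seed(seed, k * 1000 + i),
                     participant_id = fit$participants[i])
    })
    acc <- pair_accuracy(sims, design)
    acc$rep <- k
    acc
  })
}

# per-pair accuracy table: probability of choosing the symbol with the
# higher reward probability, by phase and probability pair
pair_accuracy <- function(trials, design) {
  probs <- stats::setNames(design$symbols$reward_prob, design$symbols$symbol)
  tr <- trials[!is.na(trials$chosen_symbol), ]
  p_l <- probs[tr$left_symbol]
  p_r <- probs[tr$right_symbol]
  hi <- ifelse(p_l >= p_r, tr$left_symbol, tr$right_symbol)
  pair <- paste0(round(pmax(p_l, p_r) * 100), "-",
                 round(pmin(p_l, p_r) * 100))
  tibble::tibble(phase = tr$phase, pair = pair,
                 correct = tr$chosen_symbol == hi) |>
    dplyr::group_by(.data$phase, .data$pair) |>
    dplyr::summarise(accuracy = mean(.data$correct), n = dplyr::n(),
                     .groups = "drop")
}
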