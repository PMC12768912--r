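#' Parameter-recovery experiment
#'
#' Simulates a cohort with known agent parameters drawn from the group
#' distributions, fits the hierarchical Q-learning model, and correlates the
#' generating values with the posterior-mean estimates. Reports a Pearson
#' correlation, bias and RMSE per parameter. Generating parameters come from
#' the bulk of plausible subject-level ranges (the [cohort_group_params()]
#' defaults), so the recovery claim is conditional on realistic parameter
#' spreads, not extreme tails.
#'
#' @param n_participants Cohort size (default 48).
#' @param n_blocks Training blocks per participant (default 6, i.e. 360
#'   trials).
#' @param variant Model variant to simulate from and fit (default
#'   `"two_lr"`).
#' @param seed Integer seed controlling the whole experiment.
#' @param group_params Generating distributions ([cohort_group_params()]).
#' @param chains,warmup,iter,target_accept Sampler settings passed to
#'   [fit_qlearning()].
#' @param on_bad_fit Forwarded to [fit_qlearning()].
#' @return An object of class `recovery_report`: `correlations` tibble
#'   (parameter, pearson_r, bias, rmse), `truth`, `estimates`, the fitted
#'   `ql_fit`, and the configuration.
#' @export
#' @examples
#' \donttest{
#' rec <- run_recovery(n_participants = 6, n_blocks = 1, seed = 1,
#'                     chains = 2, warmup = 150, iter = 150,
#'                     on_bad_fit = "ignore")
#' rec$correlations
#' }
run_recovery <- function(n_participants = 48, n_blocks = 6,
                         variant = c("two_lr", "one_lr"), seed,
                         group_params = cohort_group_params(), chains = 4,
                         warmup = 500, iter = 1000, target_accept = 0.8,
                         on_bad_fit = c("error", "warn", "ignore")) {
  variant <- match.arg(variant)
  on_bad_fit <- match.arg(on_bad_fit)
  cohort <- generate_cohort(
    n_participants = n_participants, group_params = group_params,
    planted = diag(3) |> `dimnames<-`(dimnames(planted_correlations())),
    seed = fanout_seed(seed, "recovery-cohort"), n_blocks = n_blocks
  )
  fit <- fit_qlearning(cohort$trials, variant = variant, chains = chains,
                       warmup = warmup, iter = iter,
                       seed = fanout_seed(seed, "recovery-fit"),
                       target_accept = target_accept,
                       on_bad_fit = on_bad_fit)
  truth <- cohort$ground_truth
  est <- posterior_means(fit)

  pars <- if (variant == "two_lr") c("alpha_reward", "alpha_loss", "beta")
          else c("alpha", "beta")
  truth_col <- function(p) switch(p, alpha = "alpha_reward", p)
  correlations <- purrr::map_dfr(pars, function(p) {
    tv <- truth[[truth_col(p)]]
    ev <- est[[p]]
    degenerate <- stats::sd(tv) == 0
    tibble::tibble(
      parameter = p,
      pearson_r = if (degenerate) NA_real_ else stats::cor(tv, ev),
      bias = mean(ev - tv),
      rmse = sqrt(mean((ev - tv)^2)),
      degenerate = degenerate
    )
  })

  structure(
    list(correlations = correlations, truth = truth, estimates = est,
         fit = fit, n_participants = n_participants,
         trials_per_participant = n_blocks * 60, variant = variant,
         seed = seed,
         sampler = list(chains = chains, warmup = warmup, iter = iter)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$variant, ":", x$n_participants,
      "participants x", x$trials_per_participant, "trials\n")
  print(x$correlations)
  invisible(x)
}
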