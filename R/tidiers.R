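#' Tidy a fitted Q-learning model
#'
#' One row per participant and parameter with posterior mean, SD and 90%
#' HDI.
#'
#' @param x A `ql_fit`.
#' @param ... Unused.
#' @return A tibble: `participant_id`, `parameter`, `estimate`, `std.error`,
#'   `hdi90_lower`, `hdi90_upper`.
#' @method tidy ql_fit
#' @export
tidy.ql_fit <- function(x, ...) {
  purrr::map_dfr(names(x$params), function(par) {
    m <- x$params[[par]]
    purrr::map_dfr(seq_along(x$participants), function(i) {
      h <- hdi(m[, i], 0.90)
      tibble::tibble(participant_id = x$participants[i], parameter = par,
                     estimate = mean(m[, i]), std.error = stats::sd(m[, i]),
                     hdi90_lower = h$lower, hdi90_upper = h$upper)
    })
  })
}

#' Fit-level summary of a Q-learning model
#'
#' @param x A `ql_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, draw counts and the
#'   convergence diagnostics.
#' @method glance ql_fit
#' @export
glance.ql_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_participants = length(x$participants),
    n_draws = nrow(x$params[[1]]),
    chains = x$chains,
    divergences = x$diagnostics$divergences,
    max_rhat = x$diagnostics$max_rhat,
    min_ebfmi = min(x$diagnostics$ebfmi),
    max_treedepth_hits = x$diagnostics$max_treedepth_hits
  )
}

#' @rdname tidy.ql_fit
#' @method tidy correlation_posterior
#' @export
tidy.correlation_posterior <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter, covariate = x$covariate_name,
    estimate = x$mean,
    hdi90_lower = x$hdi90$lower, hdi90_upper = x$hdi90$upper,
    hdi66_lower = x$hdi66$lower, hdi66_upper = x$hdi66$upper,
    p_positive = x$p_positive, r_of_means = x$r_of_means
  )
}

#' @rdname tidy.ql_fit
#' @method tidy bayes_lm
#' @export
tidy.bayes_lm <- function(x, ...) x$coef

#' @rdname glance.ql_fit
#' @method glance bayes_lm
#' @export
glance.bayes_lm <- function(x, ...) {
  tibble::tibble(n = x$n, chains = x$chains,
                 n_draws = nrow(x$draws),
                 sigma = mean(x$draws$sigma))
}

#' @rdname tidy.ql_fit
#' @method tidy affect_trend
#' @export
tidy.affect_trend <- function(x, ...) x$fixed

#' @rdname tidy.ql_fit
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$correlations

#' @rdname tidy.ql_fit
#' @method tidy loo_compare_result
#' @export
tidy.loo_compare_result <- function(x, ...) {
  tibble::tibble(elpd_a = x$elpd_a, elpd_b = x$elpd_b,
                 elpd_diff = x$elpd_diff, se_diff = x$se_diff,
                 max_pareto_k = max(x$pareto_k_a, x$pareto_k_b))
}
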