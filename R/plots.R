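#' Plot a glucose trace with its baseline and iAUC region
#'
#' @param glucose Long CGM tibble (`participant_id`, `t_min`,
#'   `glucose_mmol_l`); all participants are drawn as separate panels.
#' @param window Integration window shown (default `c(0, 120)`).
#' @return A ggplot.
#' @export
plot_glucose_traces <- function(glucose, window = c(0, 120)) {
  base <- glucose |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(baseline = fasting_glucose(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
  df <- dplyr::left_join(glucose, base, by = "participant_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min,
                                   y = .data$glucose_mmol_l)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$baseline,
      ymax = pmax(.data$glucose_mmol_l, .data$baseline)),
      fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$baseline),
                        linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::labs(x = "Minutes since glucose ingestion",
                  y = "Glucose (mmol/L)")
}

#' Posterior density of a correlation with its HDIs
#'
#' @param object A `correlation_posterior`.
#' @param ... Unused.
#' @return A ggplot of the posterior with the mean and the 66% / 90% HDIs
#'   marked beneath.
#' @method autoplot correlation_posterior
#' @export
autoplot.correlation_posterior <- function(object, ...) {
  df <- tibble::tibble(r = object$draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::annotate("segment", x = object$hdi90$lower,
                      xend = object$hdi90$upper, y = 0, yend = 0,
                      linewidth = 1) +
    ggplot2::annotate("segment", x = object$hdi66$lower,
                      xend = object$hdi66$upper, y = 0, yend = 0,
                      linewidth = 2.5) +
    ggplot2::annotate("point", x = object$mean, y = 0, size = 3) +
    ggplot2::labs(
      x = sprintf("Correlation: %s ~ %s", object$parameter,
                  object$covariate_name),
      y = "Posterior density",
      subtitle = sprintf("mean r = %.2f, 90%% HDI [%.2f, %.2f]",
                         object$mean, object$hdi90$lower,
                         object$hdi90$upper))
}

#' Truth-versus-estimate scatter for a recovery experiment
#'
#' @param object A `recovery_report`.
#' @param ... Unused.
#' @return A ggplot, one panel per parameter, with the identity line and
#'   the recovery correlation in each panel label.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  est_long <- tidyr::pivot_longer(object$estimates, -"participant_id",
                                  names_to = "parameter",
                                  values_to = "estimate")
  truth <- object$truth
  truth$alpha <- truth$alpha_reward # single-rate variant alias
  truth_long <- tidyr::pivot_longer(
    truth[, c("participant_id",
              intersect(names(truth), unique(est_long$parameter)))],
    -"participant_id", names_to = "parameter", values_to = "truth")
  df <- dplyr::inner_join(est_long, truth_long,
                          by = c("participant_id", "parameter"))
  labs <- object$correlations
  df <- dplyr::left_join(df, labs[, c("parameter", "pearson_r")],
                         by = "parameter")
  df$panel <- sprintf("%s (r = %.2f)", df$parameter, df$pearson_r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "Generating value", y = "Posterior mean")
}

#' Posterior-predictive accuracy overlay
#'
#' @param fit A `ql_fit`.
#' @param trials Observed trials to overlay.
#' @param design The `task_design` used for simulation.
#' @param n_draws,seed Passed to [posterior_predict_accuracy()].
#' @return A ggplot of predicted per-pair accuracy distributions with the
#'   observed accuracies overlaid as points.
#' @export
plot_posterior_predictive <- function(fit, trials, design, n_draws = 50,
                                      seed = 1) {
  pred <- posterior_predict_accuracy(fit, design, n_draws = n_draws,
                                     seed = seed)
  obs <- pair_accuracy(trials, design)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$pair, y = .data$accuracy)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_point(data = obs, colour = "black", size = 2) +
    ggplot2::facet_wrap(~phase, scales = "free_x") +
    ggplot2::labs(x = "Stimulus pair (reward probabilities, %)",
                  y = "P(choose higher-probability symbol)")
}

#' Affect-trend fit over trials
#'
#' @param object An `affect_trend`.
#' @param ... Unused.
#' @return A ggplot of the fitted population trend with its 90% HDI band.
#' @method autoplot affect_trend
#' @export
autoplot.affect_trend <- function(object, ...) {
  fx <- object$fixed
  b0 <- object$draws[["(Intercept)"]]
  b1 <- object$draws[["trial"]]
  tt <- seq(0, 359, by = 5)
  band <- purrr::map_dfr(tt, function(t) {
    v <- b0 + b1 * t
    h <- hdi(v, 0.90)
    tibble::tibble(trial = t + 1, mean = mean(v), lower = h$lower,
                   upper = h$upper)
  })
  ggplot2::ggplot(band, ggplot2::aes(x = .data$trial, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Trial", y = paste(object$type, "rating (%)"),
                  subtitle = sprintf("slope %+.3f points/trial",
                                     fx$estimate[fx$term == "trial"]))
}
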