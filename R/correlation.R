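#' Posterior distribution of a parameter-covariate correlation
#'
#' Propagates posterior uncertainty into a correlation: for each posterior
#' draw, the Pearson correlation between that draw's per-participant
#' parameter values and a fixed per-participant covariate is computed,
#' giving a full posterior distribution of the correlation. Summaries follow
#' the reporting convention of posterior mean, 90% and 66% highest-density
#' intervals, and the posterior probability that the correlation is
#' positive. Correlations are computed on the natural (constrained)
#' parameter scale by default.
#'
#' @param fit A `ql_fit`.
#' @param parameter Name of a subject-level parameter in the fit (e.g.
#'   `"alpha_reward"`).
#' @param covariate Named numeric vector (names = participant ids) or
#'   unnamed vector ordered as `fit$participants`; one finite value per
#'   fitted participant.
#' @param scale `"natural"` (default) or `"unconstrained"`.
#' @return An object of class `correlation_posterior`: list with `draws`
#'   (per-draw correlations), `mean`, `hdi90`, `hdi66`, `p_positive`,
#'   `r_of_means` (the correlation of the posterior-mean parameters with the
#'   covariate -- the point estimate to use when comparing against a known
#'   generating correlation, since the per-draw mean is attenuated by
#'   within-subject posterior width), `parameter`, `covariate_name`.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_participants = 6, seed = 1, n_blocks = 1)
#' fit <- fit_qlearning(cohort$trials, chains = 2, warmup = 150, iter = 150,
#'                      seed = 1, on_bad_fit = "ignore")
#' iauc <- summarize_glucose(cohort$glucose)
#' posterior_correlation(fit, "alpha_reward",
#'                       setNames(iauc$iauc, iauc$participant_id))
#' }
posterior_correlation <- function(fit, parameter, covariate,
                                  scale = c("natural", "unconstrained")) {
  stopifnot(inherits(fit, "ql_fit"))
  scale <- match.arg(scale)
  src <- if (scale == "natural") fit$params else fit$unconstrained
  if (!parameter %in% names(src)) {
    rlang::abort(paste0("parameter '", parameter, "' not in fit (has: ",
                        paste(names(src), collapse = ", "), ")"))
  }
  cov_name <- deparse(substitute(covariate))
  x <- align_covariate(covariate, fit$participants)
  if (stats::sd(x) == 0) {
    rlang::abort("covariate has zero variance; correlation undefined")
  }
  m <- src[[parameter]]
  draws <- apply(m, 1, function(row) suppressWarnings(stats::cor(row, x)))
  draws[is.na(draws)] <- 0 # zero-variance parameter draws (degenerate)
  new_correlation_posterior(draws, parameter, cov_name,
                            r_of_means = stats::cor(colMeans(m), x))
}

new_correlation_posterior <- function(draws, parameter, covariate_name,
                                      r_of_means = NA_real_) {
  structure(
    list(draws = draws, mean = mean(draws),
         hdi90 = hdi(draws, 0.90), hdi66 = hdi(draws, 0.66),
         p_positive = mean(draws > 0),
         r_of_means = r_of_means,
         parameter = parameter, covariate_name = covariate_name),
    class = "correlation_posterior"
  )
}

align_covariate <- function(covariate, ids) {
  if (!is.null(names(covariate))) {
    missing <- setdiff(ids, names(covariate))
    assert_that(length(missing) == 0,
                paste("covariate missing participants:",
                      paste(missing, collapse = ", ")))
    covariate <- covariate[ids]
  }
  assert_that(length(covariate) == length(ids),
              "covariate needs one value per fitted participant")
  assert_that(all(is.finite(covariate)), "covariate must be finite")
  as.numeric(covariate)
}

#' @export
print.correlation_posterior <- function(x, ...) {
  cat(sprintf(
    "<correlation_posterior> %s ~ %s: mean r = %.2f, 90%% HDI [%.2f, %.2f], P(r > 0) = %.2f\n",
    x$parameter, x$covariate_name, x$mean, x$hdi90$lower, x$hdi90$upper,
    x$p_positive))
  invisible(x)
}
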