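#' Simulate a trajectory of momentary affect ratings
#'
#' On-task affect (momentary happiness, confidence or engagement) is rated on
#' a 0-100 percent sliding scale once per training trial. Ratings are
#' modelled as a linear trend over trials plus independent Gaussian noise,
#' clipped to the scale limits. The intercept is anchored at trial 1, so
#' `start_percent` is the expected rating on the first trial.
#'
#' @param start_percent Expected rating at trial 1, in \[0, 100\].
#' @param slope_per_trial Change in percentage points per trial (typically a
#'   small negative number, e.g. -0.08).
#' @param noise_sd Rating noise, percentage points.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param affect_type Label attached to each rating; by default the three
#'   rating types cycle trial by trial.
#' @return A tibble with `trial`, `affect_type`, `affect_rating`.
#' @export
#' @examples
#' simulate_affect_trajectory(57.6, -0.08, 0, n_trials = 3, seed = 1)
simulate_affect_trajectory <- function(start_percent, slope_per_trial,
                                       noise_sd, n_trials, seed,
                                       affect_type = c("happiness",
                                                       "confidence",
                                                       "engagement")) {
  assert_that(start_percent >= 0 && start_percent <= 100,
              "start_percent must be in [0, 100]")
  withr_seed(seed)
  trial <- seq_len(n_trials)
  mu <- start_percent + slope_per_trial * (trial - 1)
  rating <- mu + stats::rnorm(n_trials, 0, noise_sd)
  tibble::tibble(
    trial = trial,
    affect_type = rep_len(affect_type, n_trials),
    affect_rating = pmin(pmax(rating, 0), 100)
  )
}
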