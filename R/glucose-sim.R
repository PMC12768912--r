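#' Parameters of a synthetic post-ingestion glucose curve
#'
#' Describes a smooth rise-and-decay glucose excursion following ingestion of
#' a glucose drink, as captured by a continuous glucose monitor sampling
#' every couple of minutes over a 2-hour window. The noiseless curve is a
#' gamma-like single bump
#' `fasting + peak_height * (t / time_to_peak)^shape * exp(shape * (1 - t / time_to_peak))`
#' (unit peak at `time_to_peak`), minus an optional late undershoot dip below
#' fasting, so it rises from baseline, peaks, and relaxes back.
#'
#' @param fasting Fasting glucose, mmol/L (> 0).
#' @param peak_height Peak excursion above fasting, mmol/L (>= 0).
#' @param time_to_peak Minutes from ingestion to peak.
#' @param shape Unitless bump sharpness; larger is narrower (default 2).
#' @param undershoot_depth Depth of the late dip below fasting, mmol/L
#'   (default 0).
#' @param undershoot_time Centre of the undershoot, minutes (default 100).
#' @param noise_sd Independent Gaussian sensor noise, mmol/L (default 0.2).
#' @param sampling_interval Minutes between CGM readings (default 2).
#' @param duration Minutes of monitoring after ingestion (default 120).
#' @return A list of class `glucose_curve_params`.
#' @export
glucose_curve_params <- function(fasting = 5.0, peak_height = 3.0,
                                 time_to_peak = 35, shape = 2,
                                 undershoot_depth = 0, undershoot_time = 100,
                                 noise_sd = 0.2, sampling_interval = 2,
                                 duration = 120) {
  if (!is.numeric(fasting) || fasting <= 0)
    rlang::abort("fasting must be positive")
  assert_that(peak_height >= 0, "peak_height must be non-negative")
  assert_that(sampling_interval > 0, "sampling_interval must be positive")
  assert_that(duration >= time_to_peak, "duration must cover time_to_peak")
  structure(
    list(fasting = fasting, peak_height = peak_height,
         time_to_peak = time_to_peak, shape = shape,
         undershoot_depth = undershoot_depth,
         undershoot_time = undershoot_time, noise_sd = noise_sd,
         sampling_interval = sampling_interval, duration = duration),
    class = "glucose_curve_params"
  )
}

# noiseless curve evaluated at time t (vectorised)
glucose_curve_value <- function(curve, t) {
  s <- curve$shape
  rel <- pmax(t, 0) / curve$time_to_peak
  bump <- curve$peak_height * rel^s * exp(s * (1 - rel))
  dip <- 0
  if (curve$undershoot_depth > 0) {
    dip <- curve$undershoot_depth *
      exp(-((t - curve$undershoot_time) / 20)^2)
  }
  curve$fasting + bump - dip
}

#' Generate a synthetic CGM glucose trace
#'
#' Samples the noiseless curve of [glucose_curve_params()] at the CGM
#' sampling interval over `[0, duration]` minutes, adds independent Gaussian
#' sensor noise, and returns the exact incremental area under the noiseless
#' curve (above fasting, positive part only) as ground truth. The exact iAUC
#' is obtained by locating every baseline crossing of the smooth curve with a
#' root finder and integrating the positive segments numerically to high
#' precision.
#'
#' @param curve A `glucose_curve_params` object.
#' @param seed Integer seed for the sensor noise.
#' @param participant_id Identifier stored in the trace (default `"sim"`).
#' @return A list with `trace` (tibble: `participant_id`, `t_min`,
#'   `glucose_mmol_l`) and `true_iauc` (mmol.min/L, noiseless ground truth).
#' @export
#' @examples
#' g <- generate_glucose_trace(glucose_curve_params(peak_height = 2), seed = 1)
#' g$true_iauc
generate_glucose_trace <- function(curve, seed, participant_id = "sim") {
  stopifnot(inherits(curve, "glucose_curve_params"))
  withr_seed(seed)
  times <- seq(0, curve$duration, by = curve$sampling_interval)
  clean <- glucose_curve_value(curve, times)
  noisy <- clean + stats::rnorm(length(times), 0, curve$noise_sd)
  noisy <- pmax(noisy, 0.1) # CGM readings cannot be non-positive
  trace <- tibble::tibble(
    participant_id = participant_id,
    t_min = times,
    glucose_mmol_l = noisy
  )
  list(trace = trace, true_iauc = exact_curve_iauc(curve))
}

# exact iAUC of the noiseless curve: find baseline crossings, integrate the
# positive excess on each segment
exact_curve_iauc <- function(curve) {
  f <- function(t) glucose_curve_value(curve, t) - curve$fasting
  grid <- seq(0, curve$duration, length.out = 2001)
  fg <- f(grid)
  sign_change <- which(fg[-1] * fg[-length(fg)] < 0)
  crossings <- vapply(sign_change, function(i) {
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  knots <- sort(unique(c(0, crossings, curve$duration)))
  total <- 0
  for (k in seq_len(length(knots) - 1)) {
    mid <- (knots[k] + knots[k + 1]) / 2
    if (f(mid) > 0) {
      total <- total + stats::integrate(f, knots[k], knots[k + 1],
                                        rel.tol = 1e-10,
                                        subdivisions = 500L)$value
    }
  }
  total
}
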