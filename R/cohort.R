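#' Group-level distributions for synthetic cohorts
#'
#' Defaults describe a plausible general-population sample on this task:
#' learning rates spread widely on the log-odds scale (covering roughly
#' 0.05-0.85 on the natural scale, the range typically reported for
#' subject-level estimates on probabilistic selection tasks), outcome
#' sensitivity log-normal around 5, OGTT incremental AUC log-normal around
#' 170 mmol.min/L with fasting glucose near 5 mmol/L, and affect trajectories
#' whose population intercepts and slopes match the observed task averages
#' (happiness 57.6% declining 0.08 points/trial, confidence 37.8% / -0.11,
#' engagement 65.9% / -0.21).
#'
#' @param mu_alpha_reward,sigma_alpha_reward Mean and SD of the reward
#'   learning rate on the log-odds scale.
#' @param mu_alpha_loss,sigma_alpha_loss Same for the loss learning rate.
#' @param mu_log_beta,sigma_log_beta Mean and SD of log outcome sensitivity.
#' @param iauc_log_mean,iauc_log_sd Log-scale mean and SD of the true
#'   (noiseless) incremental AUC, mmol.min/L.
#' @param fasting_mean,fasting_sd Fasting glucose distribution, mmol/L.
#' @param time_to_peak_mean,time_to_peak_sd Minutes to the glucose peak.
#' @param glucose_noise_sd CGM sensor noise, mmol/L.
#' @param affect Tibble of per-type affect trend parameters (`affect_type`,
#'   `start`, `slope`); between-person SDs `affect_intercept_sd`,
#'   `affect_slope_sd` and within-person `affect_noise_sd`.
#' @param affect_intercept_sd,affect_slope_sd,affect_noise_sd See above.
#' @return A list of class `cohort_group_params`.
#' @export
cohort_group_params <- function(
    mu_alpha_reward = qlogis(0.35), sigma_alpha_reward = 1.0,
    mu_alpha_loss = qlogis(0.25), sigma_alpha_loss = 1.0,
    mu_log_beta = log(5), sigma_log_beta = 0.5,
    iauc_log_mean = log(170), iauc_log_sd = 0.35,
    fasting_mean = 5.0, fasting_sd = 0.4,
    time_to_peak_mean = 35, time_to_peak_sd = 6,
    glucose_noise_sd = 0.2,
    affect = tibble::tibble(
      affect_type = c("happiness", "confidence", "engagement"),
      start = c(57.6, 37.8, 65.9),
      slope = c(-0.08, -0.11, -0.21)
    ),
    affect_intercept_sd = 10, affect_slope_sd = 0.04,
    affect_noise_sd = 10) {
  structure(as.list(environment()), class = "cohort_group_params")
}

#' Default planted correlation matrix
#'
#' Correlations among the reward-learning-rate latent, the metabolic latent
#' (which drives true iAUC) and the symptom latent (which drives
#' questionnaire scores). Defaults plant the study-scale effect structure:
#' 0.32 between learning rate and glucose, 0.18 between learning rate and
#' symptoms, 0.10 between glucose and symptoms.
#'
#' @param r_lr_glucose,r_lr_symptom,r_glucose_symptom Pairwise correlations.
#' @return A 3x3 correlation matrix with dimnames.
#' @export
planted_correlations <- function(r_lr_glucose = 0.32, r_lr_symptom = 0.18,
                                 r_glucose_symptom = 0.10) {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- r_lr_glucose
  m[1, 3] <- m[3, 1] <- r_lr_symptom
  m[2, 3] <- m[3, 2] <- r_glucose_symptom
  dimnames(m) <- rep(list(c("alpha_reward", "metabolic", "symptom")), 2)
  m
}

#' Generate a complete synthetic study cohort
#'
#' Emulates all three input streams of the study with known ground truth:
#' per-participant task behaviour (simulated Q-learning agents on seeded task
#' designs), CGM glucose traces over the 2-hour OGTT window, and
#' questionnaire scores. Subject-level agent parameters are drawn on the
#' unconstrained scale from the group distributions; the reward-learning-rate
#' latent, a metabolic latent and a symptom latent are drawn jointly under
#' the planted correlation matrix. True iAUC is a log-normal monotone
#' transform of the metabolic latent (the glucose curve's peak height is
#' scaled so the noiseless curve integrates exactly to it), and the PHQ-9
#' style depression score is a rounded, range-clipped monotone transform of
#' the symptom latent (0-27).
#'
#' @param n_participants Cohort size (>= 2; default 48, the study sample).
#' @param group_params A [cohort_group_params()] object.
#' @param planted A correlation matrix as from [planted_correlations()].
#' @param seed Integer global seed; every stream is derived from it.
#' @param n_blocks Training blocks per participant (default 6).
#' @param miss_rate Probability a trial is missed (default 0).
#' @return A list of class `synthetic_cohort` with elements `trials`,
#'   `glucose`, `scores`, `ground_truth`, `designs`, `planted`, `seed`.
#' @export
#' @examples
#' cohort <- generate_cohort(n_participants = 3, seed = 1, n_blocks = 1)
#' cohort$ground_truth
generate_cohort <- function(n_participants = 48,
                            group_params = cohort_group_params(),
                            planted = planted_correlations(), seed,
                            n_blocks = 6, miss_rate = 0) {
  assert_that(n_participants >= 2, "n_participants must be at least 2")
  assert_that(is.matrix(planted) && nrow(planted) == 3 &&
                isTRUE(all.equal(planted, t(planted))),
              "planted must be a symmetric 3x3 correlation matrix")
  gp <- group_params
  n <- n_participants
  traits <- cohort_latents(n, gp, planted, seed)
  ids <- traits$participant_id
  alpha_reward <- traits$alpha_reward
  alpha_loss <- traits$alpha_loss
  beta <- traits$beta
  true_iauc <- traits$true_iauc
  fasting <- traits$fasting
  time_to_peak <- traits$time_to_peak
  phq9 <- traits$phq9
  shaps <- traits$shaps
  aes <- traits$aes
  lat <- cbind(traits$latent_alpha, traits$latent_metabolic,
               traits$latent_symptom)

  withr_seed(fanout_seed(seed, "cohort-affect"))

  # per-participant affect trajectories
  aff_int <- matrix(stats::rnorm(n * 3, 0, gp$affect_intercept_sd), n, 3)
  aff_slo <- matrix(stats::rnorm(n * 3, 0, gp$affect_slope_sd), n, 3)

  trials <- vector("list", n)
  glucose <- vector("list", n)
  designs <- vector("list", n)
  n_train <- n_blocks * 60

  for (i in seq_len(n)) {
    design <- build_task_design(fanout_seed(seed, 1000 + i),
                                n_blocks = n_blocks)
    designs[[i]] <- design

    aff <- make_affect_schedule(gp, aff_int[i, ], aff_slo[i, ], n_train,
                                fanout_seed(seed, 2000 + i))
    trials[[i]] <- simulate_agent(
      design,
      agent_parameters(alpha_reward[i], alpha_loss[i], beta[i]),
      seed = fanout_seed(seed, 3000 + i),
      participant_id = ids[i], miss_rate = miss_rate, affect = aff
    )

    curve <- glucose_curve_params(
      fasting = fasting[i], peak_height = 1, time_to_peak = time_to_peak[i],
      noise_sd = gp$glucose_noise_sd
    )
    unit_area <- exact_curve_iauc(curve)
    curve$peak_height <- true_iauc[i] / unit_area
    glucose[[i]] <- generate_glucose_trace(curve,
                                           seed = fanout_seed(seed, 4000 + i),
                                           participant_id = ids[i])$trace
  }

  ground_truth <- tibble::tibble(
    participant_id = ids,
    alpha_reward = alpha_reward, alpha_loss = alpha_loss, beta = beta,
    true_iauc = true_iauc, fasting = fasting,
    latent_metabolic = lat[, 2], latent_symptom = lat[, 3],
    phq9 = phq9, shaps = shaps, aes = aes
  )

  structure(
    list(
      trials = dplyr::bind_rows(trials),
      glucose = dplyr::bind_rows(glucose),
      scores = tibble::tibble(participant_id = ids, phq9 = phq9,
                              shaps = shaps, aes = aes),
      ground_truth = ground_truth,
      designs = stats::setNames(designs, ids),
      planted = planted,
      group_params = gp,
      seed = seed
    ),
    class = "synthetic_cohort"
  )
}

# draw the per-participant traits (agent parameters, metabolic and symptom
# variables) under the planted correlation structure, without simulating
# behaviour or glucose traces
cohort_latents <- function(n, gp, planted, seed) {
  withr_seed(fanout_seed(seed, "cohort-latents"))
  # the planted matrix targets the observable scales (natural-scale learning
  # rate, iAUC, questionnaire score); inflate the latent-scale correlations
  # to undo the attenuation of the monotone transforms
  lat_corr <- deattenuate_planted(planted, gp)
  lat <- rmvnorm_chol(n, lat_corr) # columns: alpha_reward, metabolic, symptom
  eta_ar <- gp$mu_alpha_reward + gp$sigma_alpha_reward * lat[, 1]
  eta_al <- gp$mu_alpha_loss + gp$sigma_alpha_loss * stats::rnorm(n)
  eta_b <- gp$mu_log_beta + gp$sigma_log_beta * stats::rnorm(n)
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    latent_alpha = lat[, 1],
    latent_metabolic = lat[, 2],
    latent_symptom = lat[, 3],
    alpha_reward = stats::plogis(eta_ar),
    alpha_loss = stats::plogis(eta_al),
    beta = exp(eta_b),
    true_iauc = exp(gp$iauc_log_mean + gp$iauc_log_sd * lat[, 2]),
    fasting = pmax(stats::rnorm(n, gp$fasting_mean, gp$fasting_sd), 3.8),
    time_to_peak = pmin(pmax(stats::rnorm(n, gp$time_to_peak_mean,
                                          gp$time_to_peak_sd), 20), 60),
    phq9 = pmin(pmax(round(27 * stats::plogis(-1.5 + 0.9 * lat[, 3])), 0),
                27),
    shaps = pmin(pmax(round(14 * stats::plogis(-1.2 + 0.8 * (0.7 * lat[, 3] +
      sqrt(1 - 0.7^2) * stats::rnorm(n)))), 0), 14),
    aes = pmin(pmax(round(18 + 8 * (0.6 * lat[, 3] +
      sqrt(1 - 0.6^2) * stats::rnorm(n))), 0), 54)
  )
}

# correlation between a monotone transform g(X) and X for X ~ N(0, 1),
# by deterministic grid quadrature
transform_attenuation <- function(g) {
  x <- seq(-8, 8, by = 0.005)
  w <- stats::dnorm(x)
  w <- w / sum(w)
  gx <- g(x)
  m <- sum(w * gx)
  v <- sum(w * (gx - m)^2)
  sum(w * (gx - m) * x) / sqrt(v) # E[X] = 0, Var[X] = 1 under the grid
}

# inflate latent correlations so the observable-scale correlations hit the
# planted targets despite the monotone transforms
deattenuate_planted <- function(planted, gp) {
  a <- c(
    transform_attenuation(function(x) {
      stats::plogis(gp$mu_alpha_reward + gp$sigma_alpha_reward * x)
    }),
    # lognormal: corr(X, exp(sX)) = s / sqrt(exp(s^2) - 1)
    gp$iauc_log_sd / sqrt(expm1(gp$iauc_log_sd^2)),
    transform_attenuation(function(x) {
      pmin(pmax(round(27 * stats::plogis(-1.5 + 0.9 * x)), 0), 27)
    })
  )
  out <- planted
  for (i in 1:2) for (j in (i + 1):3) {
    r <- planted[i, j] / (a[i] * a[j])
    if (abs(r) >= 1) {
      rlang::abort("planted correlation too strong to realise after transform attenuation")
    }
    out[i, j] <- out[j, i] <- r
  }
  out
}

# cycling affect-type schedule with per-participant intercept/slope offsets
make_affect_schedule <- function(gp, int_offsets, slope_offsets, n_trials,
                                 seed) {
  withr_seed(seed)
  types <- gp$affect$affect_type
  type_seq <- rep_len(types, n_trials)
  trial <- seq_len(n_trials)
  rating <- numeric(n_trials)
  for (k in seq_along(types)) {
    idx <- which(type_seq == types[k])
    mu <- (gp$affect$start[k] + int_offsets[k]) +
      (gp$affect$slope[k] + slope_offsets[k]) * (trial[idx] - 1)
    rating[idx] <- mu + stats::rnorm(length(idx), 0, gp$affect_noise_sd)
  }
  tibble::tibble(trial = trial, affect_type = type_seq,
                 affect_rating = pmin(pmax(rating, 0), 100))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$ground_truth), "participants,",
      nrow(x$trials), "trial records,", nrow(x$glucose), "CGM readings\n")
  invisible(x)
}
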