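#' Configuration for a full study run
#'
#' Bundles every setting of the simulate -> iAUC -> fit -> correlate
#' pipeline into one serialisable object. A single global seed fans out to
#' per-stage seeds (recorded in the report) so stages are individually
#' reproducible.
#'
#' @param n_participants Cohort size (default 48).
#' @param n_blocks Training blocks (default 6).
#' @param planted Planted correlation matrix ([planted_correlations()]).
#' @param group_params Group distributions ([cohort_group_params()]).
#' @param variant Model used for the headline analyses (default `"two_lr"`).
#' @param compare_models Also fit the single-rate model and run the LOO
#'   comparison (default `TRUE`).
#' @param chains,warmup,iter Sampler settings.
#' @param seed Global seed.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_participants = 48, n_blocks = 6,
                         planted = planted_correlations(),
                         group_params = cohort_group_params(),
                         variant = "two_lr", compare_models = TRUE,
                         chains = 4, warmup = 500, iter = 1000, seed = 1) {
  structure(
    list(n_participants = n_participants, n_blocks = n_blocks,
         planted = planted, group_params = group_params, variant = variant,
         compare_models = compare_models, chains = chains, warmup = warmup,
         iter = iter, seed = seed),
    class = "study_config"
  )
}

#' Run the full study pipeline
#'
#' Executes the complete analysis on a synthetic cohort (or user-supplied
#' data in the same schemas): per-participant iAUC and fasting glucose from
#' the CGM traces; hierarchical model fits (dual and optionally single
#' learning rate) with diagnostics; PSIS-LOO model comparison; posterior
#' correlations of each model parameter against iAUC, fasting glucose and
#' each questionnaire score; behavioural summaries and their correlations
#' with glucose; and affect trends per rating type.
#'
#' @param config A [study_config()].
#' @param data Optional list with `trials`, `glucose`, `scores` tibbles in
#'   the documented schemas; when `NULL` a synthetic cohort is generated
#'   from the config.
#' @param on_bad_fit Forwarded to [fit_qlearning()].
#' @return A list of class `study_results` with stage outputs:
#'   `glucose_summary`, `fit` (+ `fit_one_lr`, `loo` when comparing),
#'   `correlations` (tibble of parameter x covariate posterior summaries),
#'   `behavior`, `behavior_correlations`, `affect`, `cohort` (when
#'   synthetic), `seeds`, `config`.
#' @export
run_study <- function(config = study_config(), data = NULL,
                      on_bad_fit = c("error", "warn", "ignore")) {
  on_bad_fit <- match.arg(on_bad_fit)
  stopifnot(inherits(config, "study_config"))
  seeds <- list(
    cohort = fanout_seed(config$seed, "study-cohort"),
    fit = fanout_seed(config$seed, "study-fit"),
    fit_one = fanout_seed(config$seed, "study-fit-one"),
    affect = fanout_seed(config$seed, "study-affect")
  )

  cohort <- NULL
  if (is.null(data)) {
    cohort <- generate_cohort(
      n_participants = config$n_participants,
      group_params = config$group_params, planted = config$planted,
      seed = seeds$cohort, n_blocks = config$n_blocks
    )
    data <- list(trials = cohort$trials, glucose = cohort$glucose,
                 scores = cohort$scores)
  }
  req <- c("trials", "glucose", "scores")
  assert_that(all(req %in% names(data)),
              "data must contain trials, glucose and scores")

  glucose_summary <- summarize_glucose(data$glucose)

  fit <- fit_qlearning(data$trials, variant = config$variant,
                       chains = config$chains, warmup = config$warmup,
                       iter = config$iter, seed = seeds$fit,
                       on_bad_fit = on_bad_fit)
  fit_one <- NULL
  loo_cmp <- NULL
  if (isTRUE(config$compare_models) && config$variant == "two_lr") {
    fit_one <- fit_qlearning(data$trials, variant = "one_lr",
                             chains = config$chains, warmup = config$warmup,
                             iter = config$iter, seed = seeds$fit_one,
                             on_bad_fit = on_bad_fit)
    loo_cmp <- loo_compare_models(fit, fit_one)
  }

  # posterior correlations: every model parameter x every covariate
  ids <- fit$participants
  covs <- list(
    iauc = stats::setNames(glucose_summary$iauc,
                           glucose_summary$participant_id),
    fasting = stats::setNames(glucose_summary$fasting,
                              glucose_summary$participant_id)
  )
  for (sc in setdiff(names(data$scores), "participant_id")) {
    covs[[sc]] <- stats::setNames(data$scores[[sc]],
                                  data$scores$participant_id)
  }
  correlations <- purrr::map_dfr(names(fit$params), function(par) {
    purrr::map_dfr(names(covs), function(cv) {
      cp <- posterior_correlation(fit, par, covs[[cv]])
      tibble::tibble(
        parameter = par, covariate = cv, mean_r = cp$mean,
        hdi90_lower = cp$hdi90$lower, hdi90_upper = cp$hdi90$upper,
        hdi66_lower = cp$hdi66$lower, hdi66_upper = cp$hdi66$upper,
        p_positive = cp$p_positive,
        excludes_zero_90 = cp$hdi90$lower > 0 | cp$hdi90$upper < 0,
        excludes_zero_66 = cp$hdi66$lower > 0 | cp$hdi66$upper < 0
      )
    })
  })

  behavior <- behavioral_summaries(data$trials)
  beh_aligned <- behavior[match(ids, behavior$participant_id), ]
  behavior_correlations <- purrr::map_dfr(
    c("training_accuracy", "test_accuracy", "win_stay"),
    function(stat) {
      x <- beh_aligned[[stat]]
      okx <- is.finite(x)
      r <- suppressWarnings(stats::cor(x[okx], covs$iauc[ids][okx]))
      tibble::tibble(statistic = stat, covariate = "iauc", pearson_r = r)
    })

  affect_types <- unique(stats::na.omit(data$trials$affect_type))
  affect <- purrr::map(stats::setNames(affect_types, affect_types),
                       function(ty) {
    affect_trend(data$trials, ty, seed = seeds$affect,
                 chains = config$chains, iter = config$iter)
  })

  structure(
    list(glucose_summary = glucose_summary, fit = fit,
         fit_one_lr = fit_one, loo = loo_cmp, correlations = correlations,
         behavior = behavior,
         behavior_correlations = behavior_correlations, affect = affect,
         cohort = cohort, seeds = seeds, config = config),
    class = "study_results"
  )
}

#' Render a study report
#'
#' Turns a completed [run_study()] bundle into a human-readable text summary
#' and a machine-readable list (serialisable to JSON), reporting posterior
#' means with 90% HDIs and flagging which intervals exclude zero at the 66%
#' and 90% levels.
#'
#' @param results A `study_results` object.
#' @return A list of class `study_report` with `text` (character vector of
#'   report lines) and `json` (nested list). Errors if a pipeline stage is
#'   missing.
#' @export
make_report <- function(results) {
  stopifnot(inherits(results, "study_results"))
  required <- c("glucose_summary", "fit", "correlations", "behavior",
                "affect")
  missing <- required[vapply(required, function(f) is.null(results[[f]]),
                             logical(1))]
  if (isTRUE(results$config$compare_models) && is.null(results$loo)) {
    missing <- c(missing, "loo")
  }
  if (length(missing) > 0) {
    rlang::abort(paste("incomplete results bundle; missing stages:",
                       paste(missing, collapse = ", ")))
  }

  co <- results$correlations
  lines <- c(
    "== Study report ==",
    sprintf("Participants: %d", length(results$fit$participants)),
    sprintf("Model: %s (%d total draws)", results$fit$variant,
            nrow(results$fit$params[[1]])),
    sprintf("Diagnostics: %d divergences, max split-Rhat %.3f, min E-BFMI %.2f",
            results$fit$diagnostics$divergences,
            results$fit$diagnostics$max_rhat,
            min(results$fit$diagnostics$ebfmi)),
    "",
    "Posterior correlations (mean r, 90% HDI):",
    sprintf("  %s ~ %s: r = %.2f [%.2f, %.2f]%s%s",
            co$parameter, co$covariate, co$mean_r, co$hdi90_lower,
            co$hdi90_upper,
            ifelse(co$excludes_zero_90, " *90",
                   ifelse(co$excludes_zero_66, " *66", "")),
            "")
  )
  if (!is.null(results$loo)) {
    lines <- c(lines, "",
               sprintf("LOO comparison (two_lr - one_lr): elpd diff = %.1f +/- %.1f SE",
                       results$loo$elpd_diff, results$loo$se_diff))
  }
  for (ty in names(results$affect)) {
    tr <- results$affect[[ty]]$fixed
    lines <- c(lines, sprintf(
      "Affect (%s): start %.1f%%, slope %+.3f/trial [%.3f, %.3f]",
      ty, tr$estimate[tr$term == "(Intercept)"],
      tr$estimate[tr$term == "trial"],
      tr$hdi90_lower[tr$term == "trial"],
      tr$hdi90_upper[tr$term == "trial"]))
  }

  json <- list(
    n_participants = length(results$fit$participants),
    model = results$fit$variant,
    diagnostics = list(
      divergences = results$fit$diagnostics$divergences,
      max_rhat = results$fit$diagnostics$max_rhat,
      min_ebfmi = min(results$fit$diagnostics$ebfmi)
    ),
    correlations = co,
    loo = if (!is.null(results$loo)) {
      list(elpd_diff = results$loo$elpd_diff, se = results$loo$se_diff)
    },
    behavior_correlations = results$behavior_correlations,
    affect = lapply(results$affect, function(a) a$fixed),
    seeds = results$seeds
  )

  structure(list(text = lines, json = json), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}
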