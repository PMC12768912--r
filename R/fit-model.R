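#' Fit the hierarchical Bayesian Q-learning model
#'
#' Fits the softmax Q-learning model to multi-participant training data by
#' the No-U-Turn sampler with analytic gradients. Subject-level parameters
#' live on an unconstrained scale (log-odds for learning rates, log for
#' outcome sensitivity) and are drawn non-centred from group-level normal
#' distributions with weakly-informative priors: group means N(0, 1), group
#' scales half-N(0, 1). Two variants are available: `"two_lr"` with separate
#' learning rates for positive and negative prediction errors (3 subject
#' parameters) and `"one_lr"` with a single rate (2 parameters).
#'
#' After sampling, convergence is checked against the standard thresholds —
#' zero divergences, split-Rhat < 1.1 for every fitted quantity, energy BFMI
#' > 0.3 per chain, and no iteration reaching the maximum tree depth — and
#' the fit fails loudly (or warns) if any is breached.
#'
#' @param trials Tibble of trial records for >= 1 participants (training
#'   phase enters the likelihood; each participant needs >= 1 non-missing
#'   training trial).
#' @param variant `"two_lr"` (default) or `"one_lr"`.
#' @param q_init Initial Q-value (default 0.5).
#' @param chains Number of chains (default 4).
#' @param warmup Warmup iterations per chain (default 500).
#' @param iter Post-warmup draws per chain (default 1000, for 4000 total).
#' @param seed Integer seed; fits are bit-reproducible given (data, seed,
#'   settings).
#' @param max_treedepth NUTS maximum doubling depth (default 10).
#' @param target_accept Dual-averaging target acceptance (default 0.8).
#' @param on_bad_fit `"error"` (default), `"warn"` or `"ignore"`: what to do
#'   when a diagnostic threshold is breached.
#' @return An object of class `ql_fit` with elements `params` (named list of
#'   draws-by-participant matrices on the natural scale), `unconstrained`
#'   (same on the sampling scale), `group` (tibble of group-level draws),
#'   `pointwise_loglik` (draws-by-participant log-likelihood matrix, for
#'   LOO), `diagnostics`, and metadata. Use [tidy()] for participant-level
#'   posterior means and [glance()] for fit-level summaries.
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_participants = 4, seed = 1, n_blocks = 1)
#' fit <- fit_qlearning(cohort$trials, chains = 2, warmup = 150, iter = 150,
#'                      seed = 1, on_bad_fit = "ignore")
#' tidy(fit)
#' }
fit_qlearning <- function(trials, variant = c("two_lr", "one_lr"),
                          q_init = 0.5, chains = 4, warmup = 500,
                          iter = 1000, seed, max_treedepth = 10,
                          target_accept = 0.8,
                          on_bad_fit = c("error", "warn", "ignore")) {
  variant <- match.arg(variant)
  on_bad_fit <- match.arg(on_bad_fit)
  two_lr <- variant == "two_lr"

  ids <- unique(trials$participant_id)
  n <- length(ids)
  if (n < 2) rlang::warn("fitting a hierarchy to < 2 participants; group scales are prior-dominated")
  symbols <- sort(unique(c(trials$left_symbol, trials$right_symbol)))

  per <- lapply(ids, function(id) {
    prepare_likelihood_data(trials[trials$participant_id == id, ],
                            symbols = symbols)
  })
  n_tr <- vapply(per, function(p) p$n_trials, integer(1))
  assert_that(all(n_tr >= 1),
              "every participant needs at least one non-missing training trial")

  subj <- rep(seq_len(n), n_tr)
  chosen <- unlist(lapply(per, `[[`, "chosen"))
  other <- unlist(lapply(per, `[[`, "other"))
  reward <- unlist(lapply(per, `[[`, "reward"))

  res <- rl_nuts_sample(subj, chosen, other, reward, n, length(symbols),
                        two_lr, q_init, chains, warmup, iter,
                        as.integer(seed), max_treedepth, target_accept)

  P <- if (two_lr) 3 else 2
  par_names <- if (two_lr) c("alpha_reward", "alpha_loss", "beta")
               else c("alpha", "beta")
  d <- res$draws
  S <- nrow(d)
  mu <- d[, seq_len(P), drop = FALSE]
  sigma <- exp(d[, P + seq_len(P), drop = FALSE])
  eta <- lapply(seq_len(P), function(p) {
    z <- d[, 2 * P + (p - 1) * n + seq_len(n), drop = FALSE]
    mu[, p] + sigma[, p] * z
  })
  constrain <- function(p, x) {
    if (par_names[p] == "beta") exp(x) else stats::plogis(x)
  }
  params <- stats::setNames(
    lapply(seq_len(P), function(p) {
      m <- constrain(p, eta[[p]])
      colnames(m) <- ids
      m
    }), par_names)
  unconstrained <- stats::setNames(lapply(eta, function(m) {
    colnames(m) <- ids
    m
  }), par_names)

  group <- tibble::as_tibble(
    c(stats::setNames(as.data.frame(mu), paste0("mu_", par_names)),
      stats::setNames(as.data.frame(sigma), paste0("sigma_", par_names)))
  )
  group$chain <- res$chain
  group$draw <- stats::ave(seq_len(S), res$chain, FUN = seq_along)
  group$lp <- res$lp

  aR <- params[[1]]
  aL <- if (two_lr) params[["alpha_loss"]] else params[[1]]
  bb <- params[["beta"]]
  pw <- rl_pointwise_loglik(subj, chosen, other, reward, n, length(symbols),
                            aR, aL, bb, q_init)
  colnames(pw) <- ids

  # split-Rhat over every fitted quantity: lp, group-level, subject-level
  rhat_tbl <- dplyr::bind_rows(
    tibble::tibble(quantity = "lp", rhat = split_rhat(res$lp, chains)),
    purrr::map_dfr(seq_len(P), function(p) tibble::tibble(
      quantity = c(paste0("mu_", par_names[p]),
                   paste0("sigma_", par_names[p])),
      rhat = c(split_rhat(mu[, p], chains),
               split_rhat(sigma[, p], chains))
    )),
    purrr::map_dfr(seq_len(P), function(p) tibble::tibble(
      quantity = paste0(par_names[p], "[", ids, "]"),
      rhat = apply(params[[p]], 2, split_rhat, chains = chains)
    ))
  )

  diagnostics <- list(
    divergences = sum(res$divergent),
    max_treedepth_hits = sum(res$treedepth >= max_treedepth),
    rhat = rhat_tbl,
    max_rhat = max(rhat_tbl$rhat, na.rm = TRUE),
    ebfmi = ebfmi(res$energy, chains),
    stepsize = res$stepsize,
    mean_accept = mean(res$accept_stat),
    energy = res$energy,
    treedepth = res$treedepth
  )

  fit <- structure(
    list(params = params, unconstrained = unconstrained, group = group,
         pointwise_loglik = pw, diagnostics = diagnostics,
         variant = variant, q_init = q_init, chains = chains, iter = iter,
         warmup = warmup, seed = seed, participants = ids,
         n_trials = stats::setNames(n_tr, ids), symbols = symbols),
    class = "ql_fit"
  )

  bad <- diagnostic_failures(diagnostics)
  if (length(bad) > 0 && on_bad_fit != "ignore") {
    msg <- paste0("MCMC diagnostics breached: ", paste(bad, collapse = "; "))
    if (on_bad_fit == "error") {
      cnd <- rlang::error_cnd(class = "glycolearn_diagnostic_error",
                              message = msg, diagnostics = diagnostics)
      rlang::cnd_signal(cnd)
    }
    rlang::warn(msg)
  }
  fit
}

diagnostic_failures <- function(diag) {
  bad <- character(0)
  if (diag$divergences > 0) {
    bad <- c(bad, paste(diag$divergences, "divergent transitions"))
  }
  if (is.finite(diag$max_rhat) && diag$max_rhat >= 1.1) {
    bad <- c(bad, sprintf("max split-Rhat %.3f >= 1.1", diag$max_rhat))
  }
  if (any(diag$ebfmi <= 0.3, na.rm = TRUE)) {
    bad <- c(bad, sprintf("E-BFMI %.2f <= 0.3", min(diag$ebfmi, na.rm = TRUE)))
  }
  if (diag$max_treedepth_hits > 0) {
    bad <- c(bad, paste(diag$max_treedepth_hits, "iterations hit max treedepth"))
  }
  bad
}

#' @export
print.ql_fit <- function(x, ...) {
  cat("<ql_fit>", x$variant, "model:", length(x$participants),
      "participants,", x$chains, "chains x", x$iter, "draws\n")
  cat("  divergences:", x$diagnostics$divergences,
      " max split-Rhat:", round(x$diagnostics$max_rhat, 3),
      " min E-BFMI:", round(min(x$diagnostics$ebfmi), 2), "\n")
  invisible(x)
}

#' Posterior mean subject-level parameters
#'
#' @param fit A `ql_fit`.
#' @return Tibble: `participant_id` plus one column per parameter.
#' @export
posterior_means <- function(fit) {
  stopifnot(inherits(fit, "ql_fit"))
  out <- tibble::tibble(participant_id = fit$participants)
  for (nm in names(fit$params)) out[[nm]] <- colMeans(fit$params[[nm]])
  out
}
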