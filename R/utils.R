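# internal helpers shared across modules

inv_logit <- function(x) stats::plogis(x)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a stage seed from a global seed
#'
#' Deterministic counter-based fan-out so that pipeline stages can be re-run
#' in isolation while a single global seed controls the whole run. Results
#' stay below 2^31 so they are valid R integer seeds.
#'
#' @param seed Integer global seed.
#' @param stage Stage label (character) or counter (integer).
#' @return An integer seed.
#' @export
#' @examples
#' fanout_seed(1, "fit")
fanout_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  as.integer((as.double(seed) * 48271 + as.double(stage) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

# draw one multivariate normal sample matrix (n x d) given a correlation or
# covariance matrix, via Cholesky; fails for non-positive-definite input
rmvnorm_chol <- function(n, sigma) {
  L <- tryCatch(chol(sigma), error = function(e) {
    rlang::abort("correlation matrix is not positive definite")
  })
  z <- matrix(stats::rnorm(n * ncol(sigma)), n, ncol(sigma))
  z %*% L
}

# split-Rhat (Gelman et al.): each chain split in half, then the classic
# between/within variance ratio over the 2m half-chains
split_rhat <- function(x, chains) {
  m <- matrix(x, ncol = chains)
  hl <- nrow(m) %/% 2
  if (hl < 2) return(NA_real_)
  sm <- cbind(m[seq_len(hl), , drop = FALSE],
              m[(hl + 1):(2 * hl), , drop = FALSE])
  W <- mean(apply(sm, 2, stats::var))
  B <- hl * stats::var(colMeans(sm))
  if (W <= 0) return(NA_real_)
  sqrt(((hl - 1) / hl * W + B / hl) / W)
}

# energy Bayesian fraction of missing information, one value per chain
ebfmi <- function(energy, chains) {
  e <- matrix(energy, ncol = chains)
  vapply(seq_len(chains), function(c) {
    ec <- e[, c]
    num <- sum(diff(ec)^2) / (length(ec) - 1)
    den <- stats::var(ec)
    if (den <= 0) return(NA_real_)
    num / den
  }, numeric(1))
}
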