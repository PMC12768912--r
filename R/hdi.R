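#' Highest-density interval of a sample
#'
#' Shortest interval containing at least the requested posterior mass,
#' computed by the sorted-window scan: among all windows of
#' `ceiling(mass * n)` consecutive order statistics, the narrowest one.
#' For multimodal samples this still returns a single interval (the
#' unimodal-interval convention).
#'
#' @param samples Numeric vector of >= 2 finite draws.
#' @param mass Probability mass in (0, 1) (default 0.90).
#' @return A tibble with `lower`, `upper`, `mass`.
#' @export
#' @examples
#' hdi(rnorm(4000), 0.90)
hdi <- function(samples, mass = 0.90) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2) rlang::abort("need at least 2 finite samples")
  if (!is.numeric(mass) || mass <= 0 || mass >= 1) {
    rlang::abort("mass must be in (0, 1)")
  }
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) {
    return(tibble::tibble(lower = x[1], upper = x[n], mass = mass))
  }
  # windows of k consecutive order statistics
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  tibble::tibble(lower = x[i], upper = x[i + k - 1], mass = mass)
}
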