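#' Incremental area under a glucose curve
#'
#' Computes the incremental AUC (iAUC) of an OGTT glucose trace by the
#' trapezoid rule, counting only area above the fasting baseline. For each
#' pair of consecutive readings the incremental area is
#' `(y1 + y2) / 2 * (t2 - t1)` with `y` measured as excess over baseline.
#' When one reading of a pair lies below baseline the linear segment's
#' crossing point with the baseline is found by interpolation and only the
#' positive triangle is counted; when both lie at or below baseline the
#' interval contributes nothing. A higher iAUC indicates poorer glucose
#' control.
#'
#' @param trace A data frame with time and glucose columns (defaults `t_min`,
#'   `glucose_mmol_l`), times strictly increasing, at least 2 readings.
#' @param baseline Fasting baseline, mmol/L. Defaults to
#'   [fasting_glucose()] of the same trace.
#' @param window Integration window in minutes, clipped to the trace
#'   (default `c(0, 120)`, the 2-hour protocol). Use `NULL` for the full
#'   trace.
#' @param time_col,value_col Column names.
#' @return iAUC in mmol.min/L (non-negative scalar).
#' @export
#' @examples
#' trace <- tibble::tibble(t_min = c(0, 30, 60),
#'                         glucose_mmol_l = c(5, 7, 5))
#' compute_iauc(trace) # 60: two trapezoids of 30 each
compute_iauc <- function(trace, baseline = NULL, window = c(0, 120),
                         time_col = "t_min", value_col = "glucose_mmol_l") {
  tv <- extract_trace(trace, time_col, value_col)
  if (is.null(baseline)) {
    baseline <- fasting_glucose(trace, time_col = time_col,
                                value_col = value_col, quiet = TRUE)
  }
  t <- tv$t
  y <- tv$y
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    # add interpolated boundary readings so clipping is exact
    for (b in window) {
      if (!any(t == b) && any(t < b) && any(t > b)) {
        yb <- stats::approx(t, y, xout = b)$y
        t <- c(t, b); y <- c(y, yb)
      }
    }
    o <- order(t)
    t <- t[o]; y <- y[o]
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 2) return(0)
  d <- y - baseline
  total <- 0
  for (k in seq_len(length(t) - 1)) {
    y1 <- d[k]; y2 <- d[k + 1]; dt <- t[k + 1] - t[k]
    if (y1 <= 0 && y2 <= 0) next
    if (y1 >= 0 && y2 >= 0) {
      total <- total + (y1 + y2) / 2 * dt
    } else if (y1 > 0) {
      # crosses down: positive triangle over fraction y1 / (y1 - y2)
      total <- total + y1 / 2 * dt * y1 / (y1 - y2)
    } else {
      # crosses up
      total <- total + y2 / 2 * dt * y2 / (y2 - y1)
    }
  }
  total
}

#' Fasting glucose of a trace
#'
#' Returns the reading at the largest time at or before glucose ingestion
#' (time 0). If no reading precedes time 0, the first reading is returned
#' with a warning, mirroring the use of the initial CGM reading taken before
#' the glucose drink.
#'
#' @inheritParams compute_iauc
#' @param quiet Suppress the no-pre-ingestion-reading warning.
#' @return Fasting glucose, mmol/L.
#' @export
fasting_glucose <- function(trace, time_col = "t_min",
                            value_col = "glucose_mmol_l", quiet = FALSE) {
  tv <- extract_trace(trace, time_col, value_col, min_n = 1)
  pre <- which(tv$t <= 0)
  if (length(pre) == 0) {
    if (!quiet) {
      rlang::warn("no reading at or before t = 0; using the first reading")
    }
    return(tv$y[1])
  }
  tv$y[max(pre)]
}

#' Summarise a glucose trace
#'
#' Bundles the OGTT summary measures for one trace: incremental AUC, fasting
#' glucose, peak reading, and total time spent above baseline (lengths of the
#' piecewise-linear segments exceeding the baseline, within the window).
#'
#' @inheritParams compute_iauc
#' @return A one-row tibble: `iauc`, `fasting`, `peak`, `time_above_baseline`.
#' @export
summarize_trace <- function(trace, baseline = NULL, window = c(0, 120),
                            time_col = "t_min",
                            value_col = "glucose_mmol_l") {
  tv <- extract_trace(trace, time_col, value_col)
  fasting <- fasting_glucose(trace, time_col = time_col,
                             value_col = value_col, quiet = TRUE)
  base <- baseline %||% fasting
  iauc <- compute_iauc(trace, baseline = base, window = window,
                       time_col = time_col, value_col = value_col)
  t <- tv$t; y <- tv$y
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
  }
  d <- y - base
  above <- 0
  for (k in seq_len(max(length(t) - 1, 0))) {
    y1 <- d[k]; y2 <- d[k + 1]; dt <- t[k + 1] - t[k]
    if (y1 > 0 && y2 > 0) above <- above + dt
    else if (y1 > 0) above <- above + dt * y1 / (y1 - y2)
    else if (y2 > 0) above <- above + dt * y2 / (y2 - y1)
  }
  tibble::tibble(iauc = iauc, fasting = fasting,
                 peak = max(y), time_above_baseline = above)
}

#' Per-participant glucose summaries
#'
#' Applies [summarize_trace()] to each participant in a long CGM table.
#'
#' @param glucose Data frame with `participant_id`, time and glucose columns.
#' @inheritParams compute_iauc
#' @return A tibble with one row per participant.
#' @export
summarize_glucose <- function(glucose, baseline = NULL, window = c(0, 120),
                              time_col = "t_min",
                              value_col = "glucose_mmol_l") {
  glucose |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ summarize_trace(.x, baseline = baseline,
                                          window = window,
                                          time_col = time_col,
                                          value_col = value_col)) |>
    dplyr::ungroup()
}

#' Read a CGM export
#'
#' Reads a CSV of CGM readings with columns `participant_id`, `t_min` and
#' `glucose` (or `glucose_mmol_l` / `glucose_mg_dl`). Values in mg/dL are
#' converted to mmol/L (divided by 18.016).
#'
#' @param path CSV file path.
#' @param units `"mmol_l"` (default) or `"mg_dl"`.
#' @return A tibble: `participant_id`, `t_min`, `glucose_mmol_l`.
#' @export
#' @examples
#' path <- system.file("extdata", "example_cgm.csv", package = "glycolearn")
#' cgm <- read_cgm_csv(path)
#' summarize_glucose(cgm)
read_cgm_csv <- function(path, units = c("mmol_l", "mg_dl")) {
  units <- match.arg(units)
  df <- readr::read_csv(path, show_col_types = FALSE)
  val_col <- intersect(c("glucose_mmol_l", "glucose_mg_dl", "glucose"),
                       names(df))[1]
  if (is.na(val_col)) rlang::abort("no glucose column found")
  val <- df[[val_col]]
  if (units == "mg_dl" || identical(val_col, "glucose_mg_dl")) {
    val <- val / 18.016
  }
  tibble::tibble(participant_id = as.character(df$participant_id),
                 t_min = df$t_min, glucose_mmol_l = val)
}

extract_trace <- function(trace, time_col, value_col, min_n = 2) {
  assert_that(is.data.frame(trace), "trace must be a data frame")
  assert_that(all(c(time_col, value_col) %in% names(trace)),
              paste0("trace must have columns ", time_col, " and ",
                     value_col))
  t <- trace[[time_col]]
  y <- trace[[value_col]]
  if (length(t) < min_n) {
    rlang::abort(paste("trace must contain at least", min_n, "readings"))
  }
  if (any(diff(t) <= 0)) rlang::abort("trace times must be strictly increasing")
  list(t = t, y = y)
}
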