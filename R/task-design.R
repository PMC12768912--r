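#' Build a probabilistic-selection-task design
#'
#' Constructs the trial schedule of the probabilistic selection task: six
#' stimuli with reward probabilities 0.20, 0.30, 0.40, 0.60, 0.70 and 0.80,
#' trained in three fixed pairs (80-20, 70-30, 60-40) over 6 blocks of 60
#' trials, followed by a 60-trial test phase in which every unordered stimulus
#' pairing appears twice in each left/right order and no feedback is given.
#' The symbol-to-probability assignment is a seeded random permutation, trial
#' order is shuffled within block, and left/right presentation of each pair is
#' counterbalanced.
#'
#' @param seed Integer seed controlling symbol assignment and trial order.
#' @param n_blocks Number of training blocks (default 6).
#' @param trials_per_block Trials per training block; must be divisible by 3
#'   (default 60).
#' @param points_per_win Points displayed for a rewarded choice (default 25;
#'   informational only, outcomes are coded 0/1).
#' @return An object of class `task_design`: a list with `symbols` (tibble of
#'   symbol and reward probability), `trials` (tibble with phase, block,
#'   trial, left_symbol, right_symbol) and the design constants.
#' @export
#' @examples
#' design <- build_task_design(seed = 1)
#' dplyr::count(design$trials, phase)
build_task_design <- function(seed, n_blocks = 6, trials_per_block = 60,
                              points_per_win = 25) {
  assert_that(length(seed) == 1 && is.finite(seed), "seed must be an integer")
  assert_that(trials_per_block %% 3 == 0,
              "trials_per_block must be divisible by 3")
  withr_seed(seed)

  symbols <- LETTERS[1:6]
  probs <- sample(c(0.20, 0.30, 0.40, 0.60, 0.70, 0.80))
  symbol_tbl <- tibble::tibble(symbol = symbols, reward_prob = probs)

  # fixed training pairs by probability: 80-20, 70-30, 60-40
  pair_of <- function(p_hi, p_lo) {
    c(symbols[probs == p_hi], symbols[probs == p_lo])
  }
  fixed_pairs <- list(pair_of(0.80, 0.20), pair_of(0.70, 0.30),
                      pair_of(0.60, 0.40))

  per_pair <- trials_per_block / 3
  training <- purrr::map_dfr(seq_len(n_blocks), function(b) {
    # counterbalanced orientation: half of each pair's presentations flipped
    rows <- purrr::map_dfr(seq_along(fixed_pairs), function(k) {
      pr <- fixed_pairs[[k]]
      flip <- sample(rep(c(FALSE, TRUE), length.out = per_pair))
      tibble::tibble(
        left_symbol = ifelse(flip, pr[2], pr[1]),
        right_symbol = ifelse(flip, pr[1], pr[2])
      )
    })
    rows <- rows[sample(nrow(rows)), ]
    rows$block <- b
    rows
  })
  training <- dplyr::mutate(training,
    phase = "training",
    trial = dplyr::row_number()
  )

  # test phase: all 15 unordered pairings, twice per left/right order
  combos <- utils::combn(symbols, 2)
  test <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    tibble::tibble(
      left_symbol = c(combos[1, k], combos[2, k]),
      right_symbol = c(combos[2, k], combos[1, k])
    )
  })
  test <- test[rep(seq_len(nrow(test)), 2), ]
  test <- test[sample(nrow(test)), ]
  test <- dplyr::mutate(test,
    phase = "test",
    block = NA_integer_,
    trial = dplyr::row_number()
  )

  trials <- dplyr::bind_rows(training, test)
  trials <- dplyr::select(trials, "phase", "block", "trial", "left_symbol",
                          "right_symbol")

  structure(
    list(
      symbols = symbol_tbl,
      trials = trials,
      n_blocks = n_blocks,
      trials_per_block = trials_per_block,
      points_per_win = points_per_win,
      seed = seed
    ),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat("<task_design>", x$n_blocks, "blocks x", x$trials_per_block,
      "training trials +", sum(x$trials$phase == "test"), "test trials\n")
  print(x$symbols)
  invisible(x)
}

# run code under a local RNG seed, restoring the caller's RNG state when the
# calling function exits (the saved seed is embedded by value)
withr_seed <- function(seed) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    expr <- substitute(assign(".Random.seed", o, envir = globalenv()),
                       list(o = old))
    do.call(on.exit, list(expr, TRUE), envir = parent.frame())
  }
  set.seed(seed)
  invisible(NULL)
}
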