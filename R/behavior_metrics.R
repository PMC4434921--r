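#' Probability of choosing the rich deck (PCRD) curve
#'
#' Trailing (causal) moving average of the rich-choice indicator within each
#' block and condition; blocks are never blended across the un-signaled
#' transitions.
#'
#' @param trials Trial log with `condition`, `block`, `trial_in_block`,
#'   `chose_rich`.
#' @param window Moving-average length in trials.
#' @return A `data.frame`: condition, block, trial_in_block, pcrd.
#' @export
pcrd <- function(trials, window = 10L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  stopifnot(all(c("condition", "block", "trial_in_block", "chose_rich")
                %in% names(trials)))
  out <- do.call(rbind, by(trials, list(trials$condition, trials$block),
                           function(g) {
    g <- g[order(g$trial_in_block), ]
    x <- as.numeric(g$chose_rich)
    cs <- cumsum(x)
    n <- length(x)
    i <- seq_len(n)
    lo <- pmax(i - window, 0L)
    ma <- (cs - c(0, cs)[lo + 1L]) / (i - lo)
    data.frame(condition = g$condition, block = g$block,
               trial_in_block = g$trial_in_block, pcrd = ma,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$condition, out$block, out$trial_in_block), ]
}

#' Mean PCRD in the acquisition and steady learning states
#'
#' The acquisition state covers within-block trials 1 to
#' `acquisition_trials`; the steady state covers the remainder of each
#' block. Means are unsmoothed rich-choice rates.
#'
#' @param trials Trial log with `block`, `trial_in_block`, `chose_rich`.
#' @param acquisition_trials Length of the acquisition state per block.
#' @return A list with `acquisition`, `steady` (mean PCRD, `NA` when the
#'   state is empty), the trial counts `n_acquisition`/`n_steady`, and a
#'   `steady_empty` flag.
#' @export
state_summary <- function(trials, acquisition_trials = 20L) {
  stopifnot(all(c("trial_in_block", "chose_rich") %in% names(trials)))
  acq <- trials$trial_in_block <= acquisition_trials
  if (!any(!acq))
    warning("no steady-state trials: every block is within the ",
            "acquisition window")
  max_len <- max(trials$trial_in_block)
  if (max_len < acquisition_trials)
    warning("blocks shorter than the acquisition window; ",
            "acquisition state truncated at ", max_len, " trials")
  list(acquisition = mean(trials$chose_rich[acq]),
       steady = if (any(!acq)) mean(trials$chose_rich[!acq]) else NA_real_,
       n_acquisition = sum(acq), n_steady = sum(!acq),
       steady_empty = !any(!acq))
}

#' Total game score
#'
#' Sum of the 0/1 rewards; converted to money at a 1:1 ratio in the original
#' task.
#'
#' @param trials Trial log with a `reward` column.
#' @return Total points.
#' @export
game_score <- function(trials) {
  stopifnot(all(trials$reward %in% c(0, 1)))
  sum(trials$reward)
}

#' Runs of consecutive non-reward trials before a choice shift
#'
#' Within each prime condition (one deck pair), a run is a maximal streak of
#' non-rewarded choices of the same deck. With `require_shift = TRUE` (the
#' default) only streaks terminated by switching to the other deck of the
#' pair are counted; with `FALSE`, streaks ended by a rewarded repeat of the
#' same deck or by the end of the log are counted too.
#'
#' @param trials Trial log with `condition`, `choice`, `reward`, ordered in
#'   presentation order.
#' @param require_shift Count only shift-terminated streaks?
#' @return A list: `runs` (integer run lengths, pooled over conditions),
#'   `mean` (0 when there are no runs), `n`.
#' @export
nonreward_runs <- function(trials, require_shift = TRUE) {
  stopifnot(all(c("condition", "choice", "reward") %in% names(trials)))
  runs <- integer(0)
  for (cond in unique(trials$condition)) {
    g <- trials[trials$condition == cond, ]
    deck <- NA_character_; len <- 0L
    for (t in seq_len(nrow(g))) {
      ch <- g$choice[t]; rw <- g$reward[t]
      if (len > 0L && ch != deck) {        # streak ended by a shift
        runs <- c(runs, len)
        deck <- NA_character_; len <- 0L
      }
      if (rw == 0) {
        if (len > 0L) len <- len + 1L else { deck <- ch; len <- 1L }
      } else if (len > 0L) {               # rewarded repeat ends the streak
        if (!require_shift) runs <- c(runs, len)
        deck <- NA_character_; len <- 0L
      }
    }
    if (len > 0L && !require_shift) runs <- c(runs, len)
  }
  list(runs = runs, mean = if (length(runs)) mean(runs) else 0,
       n = length(runs))
}
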