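#' Configuration of the dynamic reward task
#'
#' Describes the probabilistic two-deck-pair reward task: two prime conditions
#' (affective, neutral), each assigned to one deck pair ("Up" = decks A/B,
#' "Down" = decks C/D), with per-condition trials divided into blocks of
#' 70--90 trials separated by un-signaled reversals of the rich deck.
#'
#' Within a block the two decks of a pair pay Bernoulli rewards whose
#' probabilities stand in one of the ratios of `ratio_set` (rich:poor) and sum
#' to `total_reward_prob`; e.g. ratio 6:1 at a 60% total gives 36/70 vs 6/70.
#'
#' @param n_blocks_per_condition Number of blocks per prime condition.
#' @param trials_per_condition Trials per prime condition (total trials is
#'   twice this).
#' @param block_length_range Inclusive integer interval of admissible block
#'   lengths, in trials.
#' @param ratio_set Numeric vector of rich:poor reward-probability ratios
#'   (each > 1; the poor:rich mirror arises from the side alternation).
#' @param total_reward_prob Sum of the two reward probabilities within a pair.
#' @param training_ratio Rich:poor ratio used in the training phase.
#' @param training_min_trials Minimum number of training trials.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_blocks_per_condition = 6L,
                        trials_per_condition = 480L,
                        block_length_range = c(70L, 90L),
                        ratio_set = c(6, 3),
                        total_reward_prob = 0.6,
                        training_ratio = 6,
                        training_min_trials = 40L) {
  n_blocks_per_condition <- as.integer(n_blocks_per_condition)
  trials_per_condition <- as.integer(trials_per_condition)
  block_length_range <- as.integer(block_length_range)
  stopifnot(length(block_length_range) == 2L,
            n_blocks_per_condition >= 1L,
            length(ratio_set) >= 1L, all(ratio_set > 1))
  if (block_length_range[1] > block_length_range[2])
    stop("block_length_range must be an ordered interval")
  lo <- n_blocks_per_condition * block_length_range[1]
  hi <- n_blocks_per_condition * block_length_range[2]
  if (trials_per_condition < lo || trials_per_condition > hi)
    stop(sprintf(
      "infeasible block lengths: need %d <= trials_per_condition <= %d, got %d",
      lo, hi, trials_per_condition))
  if (!(total_reward_prob > 0 && total_reward_prob <= 1))
    stop("total_reward_prob must lie in (0, 1]")
  structure(list(
    n_blocks_per_condition = n_blocks_per_condition,
    trials_per_condition = trials_per_condition,
    block_length_range = block_length_range,
    ratio_set = as.numeric(ratio_set),
    total_reward_prob = total_reward_prob,
    training_ratio = training_ratio,
    training_min_trials = as.integer(training_min_trials)
  ), class = "task_config")
}

# decks of each pair; "Up" and "Down" refer to screen position
.pair_decks <- list(Up = c("A", "B"), Down = c("C", "D"))

.conditions <- c("affective", "neutral")

# rich/poor probabilities for ratio r:1 summing exactly to `total`
.ratio_probs <- function(r, total) {
  p_rich <- total * r / (r + 1)
  c(rich = p_rich, poor = total - p_rich)
}

# uniform sample of an integer composition of `total` into `k` parts within
# [lo, hi]: iid uniform parts conditioned on their sum, which is the uniform
# distribution on the constrained compositions
.sample_block_lengths <- function(total, k, lo, hi) {
  if (k * lo == total) return(rep(as.integer(lo), k))
  repeat {
    lens <- sample(lo:hi, k, replace = TRUE)
    if (sum(lens) == total) return(as.integer(lens))
  }
}

#' Generate a task schedule
#'
#' Draws the block structure (lengths, ratios, rich side) independently for
#' each prime condition, assigns the conditions to deck pairs (counterbalanced
#' by the random draw), and interleaves the two conditions randomly trial by
#' trial so each appears in half of the trials.
#'
#' The rich deck alternates between the two decks of a pair at every block
#' transition; the ratio magnitude is drawn uniformly from
#' `config$ratio_set`; rich and poor probabilities sum to
#' `config$total_reward_prob` by construction.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is a pure function of
#'   `(config, seed)`.
#' @return An object of class `task_schedule` with elements `blocks` (one row
#'   per condition x block), `trials` (one row per trial, in presentation
#'   order), `pair_of_condition`, `config` and `seed`.
#' @export
generate_schedule <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  set.seed(as.integer(seed))
  nb <- config$n_blocks_per_condition
  npc <- config$trials_per_condition

  # condition -> deck pair assignment, fixed for the schedule (per subject)
  pair_of_condition <- stats::setNames(sample(names(.pair_decks)), .conditions)

  blocks <- do.call(rbind, lapply(.conditions, function(cond) {
    lens <- .sample_block_lengths(npc, nb,
                                  config$block_length_range[1],
                                  config$block_length_range[2])
    ratios <- config$ratio_set[sample.int(length(config$ratio_set), nb,
                                          replace = TRUE)]
    rich_first <- sample(1:2, 1)                  # which deck of pair is rich
    rich_idx <- 1L + (rich_first + seq_len(nb)) %% 2L
    pair <- pair_of_condition[[cond]]
    decks <- .pair_decks[[pair]]
    pr <- t(vapply(ratios, .ratio_probs, numeric(2),
                   total = config$total_reward_prob))
    data.frame(
      condition = cond, pair = pair, block = seq_len(nb),
      length = lens, ratio = ratios,
      rich_deck = decks[rich_idx],
      p_rich = pr[, "rich"], p_poor = pr[, "poor"],
      stringsAsFactors = FALSE)
  }))

  # per-condition trial expansion, then random trial-by-trial interleaving
  per_cond <- lapply(.conditions, function(cond) {
    b <- blocks[blocks$condition == cond, ]
    idx <- rep(seq_len(nrow(b)), b$length)
    decks <- .pair_decks[[b$pair[1]]]
    rich <- b$rich_deck[idx]
    p1 <- ifelse(rich == decks[1], b$p_rich[idx], b$p_poor[idx])
    p2 <- ifelse(rich == decks[2], b$p_rich[idx], b$p_poor[idx])
    data.frame(
      condition = cond, pair = b$pair[1], block = idx,
      trial_in_block = unlist(lapply(b$length, seq_len)),
      deck1 = decks[1], deck2 = decks[2], p1 = p1, p2 = p2,
      rich_deck = rich, stringsAsFactors = FALSE)
  })
  order_cond <- sample(rep(1:2, each = npc))
  ord <- integer(2L * npc)
  ord[order_cond == 1L] <- seq_len(npc)
  ord[order_cond == 2L] <- npc + seq_len(npc)
  trials <- rbind(per_cond[[1]], per_cond[[2]])[ord, ]
  trials <- cbind(trial = seq_len(nrow(trials)), trials)
  rownames(trials) <- NULL

  structure(list(blocks = blocks, trials = trials,
                 pair_of_condition = pair_of_condition,
                 config = config, seed = as.integer(seed)),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("Dynamic reward task schedule:",
      nrow(x$trials), "trials,",
      nrow(x$blocks), "blocks,",
      "seed", x$seed, "\n")
  cat("Pair assignment:",
      paste(names(x$pair_of_condition), x$pair_of_condition,
            sep = " -> ", collapse = ", "), "\n")
  invisible(x)
}

#' Pre-draw Bernoulli reward outcomes for every deck and trial
#'
#' Each deck of the active pair receives one independent Bernoulli draw per
#' trial under its scheduled probability, so an agent's choice only selects
#' which pre-drawn outcome is revealed. Rewards are not baited: an outcome
#' not collected on one trial does not persist to the next.
#'
#' @param schedule A [generate_schedule()] result.
#' @param seed Integer seed.
#' @return An object of class `reward_realization`: a two-column integer
#'   matrix (`deck1`, `deck2`) aligned with `schedule$trials`, plus the seed.
#' @export
realize_rewards <- function(schedule, seed = 1L) {
  stopifnot(inherits(schedule, "task_schedule"))
  set.seed(as.integer(seed))
  n <- nrow(schedule$trials)
  out <- cbind(
    deck1 = stats::rbinom(n, 1L, schedule$trials$p1),
    deck2 = stats::rbinom(n, 1L, schedule$trials$p2))
  structure(list(outcomes = out, seed = as.integer(seed)),
            class = "reward_realization")
}

#' Identify the rich deck on a given trial
#'
#' @param schedule A `task_schedule`.
#' @param trial Trial index (1-based, presentation order).
#' @return The label of the deck with strictly higher scheduled reward
#'   probability on that trial.
#' @export
label_rich_deck <- function(schedule, trial) {
  stopifnot(inherits(schedule, "task_schedule"))
  if (trial < 1L || trial > nrow(schedule$trials))
    stop("trial index out of schedule bounds")
  row <- schedule$trials[trial, ]
  if (row$p1 == row$p2)
    stop("invalid schedule: tied reward probabilities have no rich deck")
  if (row$p1 > row$p2) row$deck1 else row$deck2
}
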