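#' Q-learning agent parameters
#'
#' @param alpha Learning rate in `[0, 1]`: the fraction of each reward
#'   prediction error incorporated into the updated expected value.
#' @param beta Choice perseveration (inverse-temperature-like), `>= 0`:
#'   0 gives random choice, larger values give more value-guided choice.
#' @param q_init Initial expected value of every deck; rewards are 0/1, so
#'   the default 0.5 is the midpoint of the outcome range.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha, beta, q_init = 0.5) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  if (!is.finite(beta) || beta < 0)
    stop("beta must be non-negative")
  if (q_init < 0 || q_init > 1)
    stop("q_init must lie in [0, 1]")
  structure(list(alpha = alpha, beta = beta, q_init = q_init),
            class = "agent_params")
}

#' Delta-rule value update
#'
#' Updates the chosen deck's expected value by `alpha` times the reward
#' prediction error `delta = reward - Q[chosen]`; unchosen decks are
#' untouched.
#'
#' @param q Named numeric vector of per-deck expected values.
#' @param chosen Name of the chosen deck.
#' @param reward Observed outcome, 0 or 1.
#' @param alpha Learning rate in `[0, 1]`.
#' @return A list with the updated `q` and the prediction error `delta`.
#' @export
q_update <- function(q, chosen, reward, alpha) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  stopifnot(reward %in% c(0, 1), chosen %in% names(q))
  delta <- reward - q[[chosen]]
  q[[chosen]] <- q[[chosen]] + alpha * delta
  list(q = q, delta = unname(delta))
}

#' Softmax (Boltzmann) choice probability
#'
#' Probability of choosing the first of two decks,
#' `exp(beta*Q1) / (exp(beta*Q1) + exp(beta*Q2))`, evaluated in the
#' numerically stable logistic form so that no overflow occurs for
#' `beta * Q` up to several hundred.
#'
#' @param q Numeric vector of length 2: expected values of the active pair.
#' @param beta Choice perseveration, `>= 0`.
#' @return Probability of choosing the first deck.
#' @export
choice_prob <- function(q, beta) {
  if (!is.finite(beta) || beta < 0)
    stop("beta must be non-negative")
  stopifnot(length(q) == 2L)
  d <- beta * (q[[1]] - q[[2]])
  # evaluate the logistic on the non-negative side only, so that the two
  # decks' probabilities are exact floating-point complements
  if (d >= 0) stats::plogis(d) else 1 - stats::plogis(-d)
}

#' Simulate a Q-learning agent on a schedule
#'
#' Plays the task forward: on every trial the agent chooses within the active
#' pair with [choice_prob()], collects the pre-drawn outcome of the chosen
#' deck, and applies [q_update()]. Q values are maintained separately per
#' deck pair and carried across the un-signaled block transitions without
#' reset.
#'
#' @param params An [agent_params()].
#' @param schedule A [generate_schedule()] result.
#' @param rewards A matching [realize_rewards()] result.
#' @param seed Integer seed for the choice draws.
#' @return A `data.frame` of trial records: trial, condition, pair, block,
#'   trial_in_block, choice, reward, `q1`/`q2` (pre-choice values of the
#'   pair's decks), `p_choice` (probability of the deck actually chosen),
#'   `delta` (reward prediction error), `rich_deck`, `chose_rich`.
#' @export
simulate_agent <- function(params, schedule, rewards, seed = 1L) {
  stopifnot(inherits(params, "agent_params"),
            inherits(schedule, "task_schedule"),
            inherits(rewards, "reward_realization"))
  tr <- schedule$trials
  n <- nrow(tr)
  if (nrow(rewards$outcomes) != n)
    stop("schedule and reward realization have different lengths")
  set.seed(as.integer(seed))
  u <- stats::runif(n)

  q <- stats::setNames(rep(params$q_init, 4), unlist(.pair_decks))
  choice <- character(n); rew <- integer(n)
  q1 <- q2 <- p_choice <- delta <- numeric(n)
  for (t in seq_len(n)) {
    d <- c(tr$deck1[t], tr$deck2[t])
    q1[t] <- q[[d[1]]]; q2[t] <- q[[d[2]]]
    p1 <- choice_prob(c(q1[t], q2[t]), params$beta)
    pick <- if (u[t] < p1) 1L else 2L
    choice[t] <- d[pick]
    p_choice[t] <- if (pick == 1L) p1 else 1 - p1
    rew[t] <- rewards$outcomes[t, pick]
    up <- q_update(q, choice[t], rew[t], params$alpha)
    q <- up$q; delta[t] <- up$delta
  }
  data.frame(tr[, c("trial", "condition", "pair", "block", "trial_in_block")],
             choice = choice, reward = rew, q1 = q1, q2 = q2,
             p_choice = p_choice, delta = delta,
             rich_deck = tr$rich_deck,
             chose_rich = choice == tr$rich_deck,
             stringsAsFactors = FALSE)
}

# encode a trial log into the integer vectors the C++ likelihood consumes
.encode_trials <- function(trials) {
  stopifnot(all(c("pair", "choice", "reward") %in% names(trials)))
  pair_levels <- unique(trials$pair)
  pair_idx <- match(trials$pair, pair_levels)
  choice_idx <- integer(nrow(trials))
  for (k in seq_along(pair_levels)) {
    decks <- .pair_decks[[pair_levels[k]]]
    sel <- pair_idx == k
    choice_idx[sel] <- match(trials$choice[sel], decks)
  }
  if (anyNA(choice_idx)) stop("choice labels do not belong to their pair")
  list(pair_idx = as.integer(pair_idx),
       choice_idx = as.integer(choice_idx),
       reward = as.integer(trials$reward),
       n_pairs = length(pair_levels))
}

#' Log-likelihood of observed choices under the Q-learning model
#'
#' Replays the Q values from `q_init` given the observed choices and rewards
#' (never trusting Q fields stored in the log) and sums the log softmax
#' probability of each observed choice.
#'
#' @param params An [agent_params()].
#' @param trials A trial log with columns `pair`, `choice`, `reward`,
#'   ordered in presentation order.
#' @return The summed log-probability (always `<= 0`).
#' @export
log_likelihood <- function(params, trials) {
  stopifnot(inherits(params, "agent_params"))
  if (nrow(trials) == 0L) {
    warning("empty trial list: log-likelihood defined as 0")
    return(0)
  }
  enc <- .encode_trials(trials)
  .ll_qlearn_cpp(enc$pair_idx, enc$choice_idx, enc$reward,
                 params$alpha, params$beta, params$q_init, enc$n_pairs)
}
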