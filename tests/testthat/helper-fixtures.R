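# shared fixtures and independent oracles

small_task <- function() task_config(n_blocks_per_condition = 2L,
                                     trials_per_condition = 80L,
                                     block_length_range = c(35L, 45L))

# hand-built trial log on one pair: choices/rewards given, columns as the
# package emits them
manual_trials <- function(choice, reward, pair = "Up",
                          condition = "neutral") {
  n <- length(choice)
  data.frame(trial = seq_len(n), condition = rep(condition, n),
             pair = rep(pair, n), block = rep(1L, n),
             trial_in_block = seq_len(n),
             choice = choice, reward = reward, stringsAsFactors = FALSE)
}

# independent R replay of the Q-learning likelihood: per-trial softmax
# probabilities multiplied explicitly (brute force)
brute_force_ll <- function(alpha, beta, trials, q_init = 0.5) {
  decks <- list(Up = c("A", "B"), Down = c("C", "D"))
  q <- c(A = q_init, B = q_init, C = q_init, D = q_init)
  p <- numeric(nrow(trials))
  for (t in seq_len(nrow(trials))) {
    d <- decks[[trials$pair[t]]]
    w <- exp(beta * q[d])
    p[t] <- w[[trials$choice[t]]] / sum(w)
    ch <- trials$choice[t]
    q[[ch]] <- q[[ch]] + alpha * (trials$reward[t] - q[[ch]])
  }
  log(prod(p))
}

# flat wave with named channels for peak tests
flat_wave <- function(channels = "Fz", times = 0:700) {
  structure(matrix(0, length(channels), length(times),
                   dimnames = list(channels, NULL)),
            class = "erp_average", times = times, rate = 1000,
            n_epochs = 1L)
}
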