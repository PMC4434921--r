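#' Specification of a synthetic subject group
#'
#' True group-level generating values for the Q-learning parameters and
#' target ERP component amplitudes, used by [synth_cohort()] and
#' [synth_epochs()]. The three labels mirror the priming design: NN
#' (neutral-neutral control), AN (angry-neutral), HN (happy-neutral).
#'
#' FRN amplitudes are named per channel and give the peak of the noise-free
#' difference wave embedded in omission epochs; distinct values for the
#' expectation-consistent and expectation-violating sides are optional.
#'
#' @param label Group label, `"NN"`, `"AN"` or `"HN"`.
#' @param mu_alpha,sigma_alpha Group mean and SD of the learning rate.
#' @param mu_beta,sigma_beta Group mean and SD of the choice perseveration.
#' @param n_subjects Number of subjects.
#' @param frn_amp Named vector, channel -> target FRN peak (microvolts,
#'   negative) embedded in every omission epoch.
#' @param frn_expected_amp,frn_unexpected_amp Optional per-class overrides
#'   for expected-omission and unexpected-omission epochs.
#' @param n170_amp Named vector of N170 peaks at the occipito-temporal
#'   channels (prime-locked, negative; default right-lateralized).
#' @param eep_amp Named vector of early-emotional-positivity peaks at
#'   midline channels (prime-locked, positive).
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label = c("NN", "AN", "HN"),
                       mu_alpha = 0.3, sigma_alpha = 0.1,
                       mu_beta = 3, sigma_beta = 1,
                       n_subjects = 12L,
                       frn_amp = NULL,
                       frn_expected_amp = NULL,
                       frn_unexpected_amp = NULL,
                       n170_amp = c(P7 = -4, P8 = -5),
                       eep_amp = c(Fz = 3, Cz = 2.8, Pz = 2.2)) {
  label <- match.arg(label)
  if (is.null(frn_amp)) {
    # group-level General FRN magnitudes, scaled over the fronto-central
    # topography (Fz < FCz ~ Cz)
    base <- c(NN = -6.50, AN = -7.33, HN = -7.23)[[label]]
    frn_amp <- base * c(Fz = 0.90, FCz = 1.00, Cz = 1.01)
  }
  stopifnot(sigma_alpha > 0 || sigma_alpha == 0,
            sigma_beta > 0 || sigma_beta == 0,
            n_subjects >= 1L, all(is.finite(frn_amp)))
  structure(list(label = label,
                 mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 mu_beta = mu_beta, sigma_beta = sigma_beta,
                 n_subjects = as.integer(n_subjects),
                 frn_amp = frn_amp,
                 frn_expected_amp = frn_expected_amp %||% frn_amp,
                 frn_unexpected_amp = frn_unexpected_amp %||% frn_amp,
                 n170_amp = n170_amp, eep_amp = eep_amp),
            class = "group_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic EEG noise specification
#'
#' @param model `"white"` (Gaussian, analytically tractable peak-bias
#'   behavior) or `"one_over_f"` (1/f-shaped spectrum for more realistic
#'   background activity).
#' @param sd Noise standard deviation in microvolts.
#' @param montage Channel names.
#' @param rate Sampling rate in Hz.
#' @return An object of class `eeg_noise_spec`.
#' @export
eeg_noise_spec <- function(model = c("white", "one_over_f"), sd = 5,
                           montage = c("Fz", "FCz", "Cz", "Pz", "P7", "P8"),
                           rate = 1000) {
  model <- match.arg(model)
  stopifnot(sd > 0, length(montage) >= 1L, rate > 0)
  structure(list(model = model, sd = sd, montage = montage, rate = rate),
            class = "eeg_noise_spec")
}

# noise matrix, channels x samples, at the spec's SD
.noise_matrix <- function(noise, n_chan, n_samp) {
  if (noise$model == "white")
    return(matrix(stats::rnorm(n_chan * n_samp, 0, noise$sd), n_chan, n_samp))
  # 1/f: shape white noise in the frequency domain, then rescale to sd
  t(vapply(seq_len(n_chan), function(ch) {
    w <- stats::rnorm(n_samp)
    f <- stats::fft(w)
    freq <- pmax(seq(0, n_samp - 1) * noise$rate / n_samp, noise$rate / n_samp)
    freq <- pmin(freq, noise$rate - freq)  # mirror for the negative half
    x <- Re(stats::fft(f / sqrt(freq), inverse = TRUE)) / n_samp
    x / stats::sd(x) * noise$sd
  }, numeric(n_samp)))
}

# unit-peak Gaussian bump sampled at `times` ms
.bump <- function(times, center_ms, sd_ms) {
  exp(-(times - center_ms)^2 / (2 * sd_ms^2))
}

#' Simulate a cohort of Q-learning subjects
#'
#' Draws each subject's learning rate from a normal truncated to `[0,1]` and
#' choice perseveration from a normal truncated to `[0, Inf)` (a degenerate
#' SD of 0 collapses to a point mass with a warning), then plays every
#' subject through an independently generated schedule and reward
#' realization.
#'
#' @param spec A [group_spec()].
#' @param task A [task_config()].
#' @param seed Integer seed; the cohort is a pure function of
#'   `(spec, task, seed)`.
#' @return A list: `trials` (per-subject trial logs), `truth` (`data.frame`
#'   of subject, alpha, beta), `schedules`, `spec`, `seed`.
#' @export
synth_cohort <- function(spec, task = task_config(), seed = 1L) {
  stopifnot(inherits(spec, "group_spec"), inherits(task, "task_config"))
  set.seed(as.integer(seed))
  n <- spec$n_subjects
  if (spec$sigma_alpha == 0 || spec$sigma_beta == 0)
    warning("degenerate group SD: parameters collapse to a point mass")
  alpha <- if (spec$sigma_alpha > 0)
    .rtnorm(n, spec$mu_alpha, spec$sigma_alpha, 0, 1)
  else rep(spec$mu_alpha, n)
  beta <- if (spec$sigma_beta > 0)
    .rtnorm(n, spec$mu_beta, spec$sigma_beta, 0, Inf)
  else rep(spec$mu_beta, n)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n), n, 3L)

  schedules <- vector("list", n)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    schedules[[i]] <- generate_schedule(task, sub_seeds[i, 1])
    rw <- realize_rewards(schedules[[i]], sub_seeds[i, 2])
    tr <- simulate_agent(agent_params(alpha[i], beta[i]),
                         schedules[[i]], rw, sub_seeds[i, 3])
    tr$subject <- i
    trials[[i]] <- tr
  }
  list(trials = trials,
       truth = data.frame(subject = seq_len(n), alpha = alpha, beta = beta),
       schedules = schedules, spec = spec, seed = as.integer(seed))
}

#' Synthesize feedback- or prime-locked EEG epochs for a trial log
#'
#' Builds one epoch per trial directly in the epoch representation: noise
#' from the spec plus, for feedback-locked epochs, a Gaussian-shaped
#' negativity (center 280 ms, SD 40 ms) added to omission epochs at the
#' channels named in the group spec, scaled so the noise-free difference
#' wave's negative peak in 200--400 ms equals the spec's target amplitude.
#' Prime-locked epochs embed the N170 (negative, 150 ms, SD 20 ms,
#' occipito-temporal) and the EEP (positive, 150 ms, SD 15 ms, midline).
#'
#' Epochs produced here are "post-filtering" surrogates: band limiting of a
#' recorded signal is not simulated, so pipeline stages downstream of the
#' continuous filter can be exercised exactly. Use [synth_feedback_record()]
#' for a continuous record that runs through the full filter-then-epoch
#' path.
#'
#' @param trials A trial log (one subject or concatenated) with `reward` and
#'   `chose_rich` columns.
#' @param spec A [group_spec()].
#' @param noise An [eeg_noise_spec()].
#' @param locked `"feedback"` (window −100..700 ms) or `"prime"`
#'   (−100..500 ms).
#' @param seed Integer seed.
#' @return A labeled [epoch_set()] (labels: `outcome_class`, `condition`,
#'   `reward`, `state`).
#' @export
synth_epochs <- function(trials, spec, noise = eeg_noise_spec(),
                         locked = c("feedback", "prime"), seed = 1L) {
  locked <- match.arg(locked)
  stopifnot(inherits(spec, "group_spec"), inherits(noise, "eeg_noise_spec"))
  needed <- if (locked == "feedback")
    names(spec$frn_amp) else c(names(spec$n170_amp), names(spec$eep_amp))
  if (!all(needed %in% noise$montage))
    stop("montage is missing required channels: ",
         paste(setdiff(needed, noise$montage), collapse = ", "))
  set.seed(as.integer(seed))
  window <- if (locked == "feedback") c(-100, 700) else c(-100, 500)
  times <- seq(window[1], window[2], by = 1000 / noise$rate)
  nt <- length(times); nc <- length(noise$montage)
  n <- nrow(trials)
  cls <- classify_outcome(trials)

  data <- array(0, c(n, nc, nt))
  comp <- matrix(0, nc, nt, dimnames = list(noise$montage, NULL))
  if (locked == "prime") {
    comp[names(spec$n170_amp), ] <-
      outer(spec$n170_amp, .bump(times, 150, 20))
    comp[names(spec$eep_amp), ] <- comp[names(spec$eep_amp), ] +
      outer(spec$eep_amp, .bump(times, 150, 15))
  }
  bump <- .bump(times, 280, 40)
  for (k in seq_len(n)) {
    ep <- .noise_matrix(noise, nc, nt)
    if (locked == "feedback") {
      amp <- switch(as.character(cls[k]),
                    "expected-omission" = spec$frn_expected_amp,
                    "unexpected-omission" = spec$frn_unexpected_amp,
                    NULL)
      if (!is.null(amp)) {
        idx <- match(names(amp), noise$montage)
        ep[idx, ] <- ep[idx, ] + outer(unname(amp), bump)
      }
    } else {
      ep <- ep + comp
    }
    data[k, , ] <- ep
  }
  labels <- data.frame(
    outcome_class = cls,
    condition = trials$condition,
    reward = trials$reward,
    state = ifelse(trials$trial_in_block <= 20, "acquisition", "steady"),
    stringsAsFactors = FALSE)
  epoch_set(data, noise$montage, noise$rate, window, labels)
}

#' Synthesize a continuous feedback-locked EEG record
#'
#' Lays out one feedback event per trial along a continuous multi-channel
#' record (inter-stimulus interval `isi_ms`), adds background noise over the
#' whole record, and adds the FRN negativity (Gaussian, center 280 ms after
#' each omission event, SD 40 ms) scaled per channel to the target peak
#' amplitudes. The record is meant to be run through the full preprocessing
#' path: [bandpass()] on the continuous signal, [epoch_signal()],
#' [baseline_correct()], [reject_artifacts()], [frn_analysis()].
#'
#' @param outcome_class Character/factor vector of outcome classes, one per
#'   event, from the [classify_outcome()] vocabulary.
#' @param amp Named vector, channel -> noise-free difference-wave peak in
#'   microvolts, applied to every omission event. A named list with entries
#'   `"expected-omission"` and `"unexpected-omission"` gives class-specific
#'   amplitudes.
#' @param noise An [eeg_noise_spec()].
#' @param isi_ms Event spacing in ms.
#' @param pad_ms Silent padding at both ends of the record in ms.
#' @param seed Integer seed.
#' @return A list: `record` ([eeg_record()]), `events_ms`, `labels`
#'   (`data.frame` with `outcome_class`).
#' @export
synth_feedback_record <- function(outcome_class, amp,
                                  noise = eeg_noise_spec(),
                                  isi_ms = 1000, pad_ms = 2000, seed = 1L) {
  stopifnot(inherits(noise, "eeg_noise_spec"))
  cls <- as.character(outcome_class)
  if (!is.list(amp))
    amp <- list("expected-omission" = amp, "unexpected-omission" = amp)
  for (a in amp)
    if (!all(names(a) %in% noise$montage))
      stop("montage is missing required channels: ",
           paste(setdiff(names(a), noise$montage), collapse = ", "))
  set.seed(as.integer(seed))
  n_ev <- length(cls)
  rate <- noise$rate
  events_ms <- pad_ms + (seq_len(n_ev) - 1) * isi_ms
  n_samp <- round((2 * pad_ms + n_ev * isi_ms) * rate / 1000)
  nc <- length(noise$montage)
  sig <- .noise_matrix(noise, nc, n_samp)
  t_ms <- (seq_len(n_samp) - 1) * 1000 / rate
  # add each omission bump over its local support only (±4 SD)
  half <- round(4 * 40 * rate / 1000)
  for (k in seq_len(n_ev)) {
    a <- amp[[cls[k]]]
    if (is.null(a)) next
    c0 <- round((events_ms[k] + 280) * rate / 1000) + 1L
    span <- max(1L, c0 - half):min(n_samp, c0 + half)
    b <- .bump(t_ms[span], events_ms[k] + 280, 40)
    idx <- match(names(a), noise$montage)
    sig[idx, span] <- sig[idx, span] + outer(unname(a), b)
  }
  list(record = eeg_record(sig, noise$montage, rate),
       events_ms = events_ms,
       labels = data.frame(outcome_class = factor(cls,
                                                  levels = .outcome_levels),
                           stringsAsFactors = FALSE))
}

#' Run the standard feedback preprocessing path on a continuous record
#'
#' Bandpass-filters the continuous record, segments it around the events,
#' baseline-corrects, and applies amplitude-threshold rejection --- the
#' preprocessing order used for recorded EEG, where the highpass must act on
#' the continuous signal.
#'
#' @param bundle A [synth_feedback_record()] result, or any list with
#'   `record`, `events_ms`, `labels`.
#' @param low,high Bandpass edges in Hz.
#' @param window Epoch window in ms.
#' @param threshold Artifact rejection threshold in microvolts.
#' @return A list: `epochs` (clean labeled [epoch_set()]) and `rejection`
#'   report.
#' @export
preprocess_feedback <- function(bundle, low = 0.1, high = 40,
                                window = c(-100, 700), threshold = 50) {
  rec <- bandpass(bundle$record, low, high)
  ep <- epoch_signal(rec, bundle$events_ms, window, bundle$labels)
  ep <- baseline_correct(ep)
  rej <- reject_artifacts(ep, threshold, by = "outcome_class")
  list(epochs = rej$epochs, rejection = rej$report)
}
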