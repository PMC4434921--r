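test_that("bandpass preserves the passband and rejects DC and 80 Hz", {
  rate <- 1000
  t <- seq_len(30000) / rate
  s10 <- sin(2 * pi * 10 * t)
  y <- bandpass(s10, 0.1, 40, rate)
  mid <- 10000:20000
  expect_lt(abs(max(abs(y[mid])) - 1), 0.01)
  # DC removed on a long record (generous edge trim: 0.1 Hz settles slowly)
  yd <- bandpass(rep(7, 30000), 0.1, 40, rate)
  expect_lt(max(abs(yd[mid])) / 7, 0.01)
  s80 <- sin(2 * pi * 80 * t)
  y80 <- bandpass(s80, 0.1, 40, rate)
  expect_lt(max(abs(y80[mid])), 0.1)   # > 90% attenuation
  expect_error(bandpass(s10, 0.1, 600, rate), "Nyquist")
  expect_error(bandpass(s10, 50, 40, rate), "Nyquist")
})

test_that("epoching counts, aligns and drops edge events", {
  rec <- eeg_record(matrix(0, 1, 10000), "Fz", 1000)
  ep <- epoch_signal(rec, c(2000, 4000, 6000), c(-100, 700))
  expect_equal(dim(ep$data), c(3L, 1L, 801L))
  expect_equal(ep$times[1], -100)
  expect_equal(ep$times[801], 700)
  expect_warning(
    ep2 <- epoch_signal(rec, c(50, 3000), c(-100, 700)),
    "1 event")
  expect_equal(dim(ep2$data)[1], 1L)
  # impulse at the event lands on the 0 ms sample
  sig <- matrix(0, 1, 10000); sig[1, 5001] <- 9   # sample 5001 = 5000 ms
  ep3 <- epoch_signal(eeg_record(sig, "Fz"), 5000, c(-100, 700))
  expect_equal(ep3$data[1, 1, which(ep3$times == 0)], 9)
  expect_true(all(ep3$data[1, 1, ep3$times != 0] == 0))
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  mk <- function(f) {
    d <- array(0, c(1, 1, 801))
    d[1, 1, ] <- f(seq(-100, 700))
    epoch_set(d, "Cz", 1000, c(-100, 700))
  }
  const <- baseline_correct(mk(function(t) rep(7, length(t))))
  expect_equal(max(abs(const$data)), 0)
  bumped <- mk(function(t) 5 + 3 * exp(-(t - 300)^2 / 800))
  bc <- baseline_correct(bumped)
  expect_lt(abs(mean(bc$data[1, 1, bc$times < 0])), 1e-9)
  expect_equal(max(bc$data[1, 1, ]), 3, tolerance = 1e-6)
  expect_equal(bc$data, baseline_correct(bc)$data)   # idempotent
  no_pre <- mk(function(t) rep(1, length(t)))
  no_pre$times <- no_pre$times + 200     # shift so nothing precedes the event
  expect_error(baseline_correct(no_pre), "pre-stimulus")
})

test_that("artifact rejection applies the threshold and is monotone", {
  d <- array(0, c(3, 2, 100))
  d[1, 1, 50] <- 60        # one 60 uV sample anywhere rejects the epoch
  d[2, 2, ] <- 49          # bounded by 49 uV is kept
  d[3, 1, ] <- rnorm(100)
  ep <- epoch_set(d, c("Fz", "Cz"), 1000, c(-10, 89),
                  labels = data.frame(outcome_class = c("a", "b", "b")))
  r50 <- reject_artifacts(ep, 50, by = "outcome_class")
  expect_equal(r50$report$n_rejected, 1L)
  expect_equal(dim(r50$epochs$data)[1], 2L)
  expect_equal(unname(r50$report$per_level["a"]), 1)
  rInf <- reject_artifacts(ep, 1e9)
  expect_equal(rInf$report$n_rejected, 0L)
  # kept set grows with the threshold
  kept <- vapply(c(10, 49, 50, 70), function(th)
    dim(reject_artifacts(ep, th)$epochs$data)[1], numeric(1))
  expect_true(all(diff(kept) >= 0))
  all_gone <- reject_artifacts(epoch_set(array(99, c(2, 2, 10)),
                                         c("Fz", "Cz"), 1000, c(-5, 4)), 50)
  expect_true(all_gone$report$all_rejected)
  expect_error(average_epochs(all_gone$epochs, integer(0)), "empty")
})

test_that("outcome classification follows the rich/poor x reward table", {
  tr <- data.frame(reward = c(1, 0, 1, 0),
                   chose_rich = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(as.character(classify_outcome(tr)),
               c("expected-delivery", "expected-omission",
                 "unexpected-delivery", "unexpected-omission"))
  # resolution through the schedule, including the tie error
  sch <- generate_schedule(small_task(), 41)
  rw <- realize_rewards(sch, 42)
  log <- simulate_agent(agent_params(0.3, 3), sch, rw, 43)
  log$chose_rich <- NULL; log$rich_deck <- NULL
  cls <- classify_outcome(log, sch)
  expect_equal(as.character(cls)[log$reward == 1 &
                                 log$choice == sch$trials$rich_deck][1],
               "expected-delivery")
  tie <- sch; tie$trials$p1 <- tie$trials$p2
  expect_error(classify_outcome(log[1, ], tie), "tie")
})

test_that("difference waves are linear and antisymmetric", {
  w <- flat_wave("Fz", 0:100)
  a <- w; a[1, ] <- sin(0:100 / 5)
  b <- a; b[1, ] <- a[1, ] + 5
  expect_equal(max(abs(difference_wave(a, a))), 0)
  expect_equal(unclass(difference_wave(a, b))[1, ], rep(-5, 101))
  expect_equal(unclass(difference_wave(a, b)),
               -unclass(difference_wave(b, a)))
  other <- flat_wave("Cz", 0:100)
  expect_error(difference_wave(a, other), "channels")
})

test_that("peak extraction equals a brute-force scan and breaks ties early", {
  t <- seq(-100, 700)
  w <- flat_wave(c("Fz", "FCz"), t)
  w[1, ] <- -7 * exp(-(t - 280)^2 / (2 * 30^2))
  pk <- peak_component(w, c(200, 400), "negative")
  expect_equal(pk$amplitude, c(-7, 0))
  expect_equal(pk$latency[1], 280)
  expect_equal(pk$latency[2], 200)        # flat channel: earliest sample
  # EEP-style positive peak
  w2 <- flat_wave("Pz", seq(-100, 500))
  w2[1, ] <- 4 * exp(-(attr(w2, "times") - 150)^2 / (2 * 15^2))
  pk2 <- peak_component(w2, c(120, 180), "positive")
  expect_equal(pk2$amplitude, 4)
  expect_equal(pk2$latency, 150)
  # oracle: exhaustive scan over in-window samples on random waves
  set.seed(6)
  for (k in 1:10) {
    w3 <- flat_wave("Cz", t)
    w3[1, ] <- rnorm(length(t))
    win <- sort(sample(seq(-100, 700), 2))
    if (diff(win) < 5) next
    pk3 <- peak_component(w3, win, "negative")
    sel <- t >= win[1] & t <= win[2]
    expect_identical(pk3$amplitude, min(w3[1, sel]))
    expect_identical(pk3$latency, t[sel][which.min(w3[1, sel])])
  }
  expect_error(peak_component(w, c(900, 950)), "empty")
})

test_that("frn_analysis recovers an embedded dip and keeps its books", {
  tr <- data.frame(condition = "neutral", block = 1, trial_in_block = 1:200,
                   reward = rep(c(1, 0), 100),
                   chose_rich = rep(c(TRUE, FALSE), 100))
  spec <- group_spec("NN", frn_amp = c(FCz = -8))
  noise <- eeg_noise_spec(sd = 5, montage = c("Fz", "FCz", "Cz"))
  ep <- synth_epochs(tr, spec, noise, seed = 91)
  res <- frn_analysis(ep, "general", channels = "FCz")
  expect_false(res$missing)
  expect_equal(res$n_minuend, 100)
  expect_equal(res$n_subtrahend, 100)
  # noise on the averages is ~0.7 uV; allow 3 SD plus the peak-picking bias
  expect_lt(abs(res$peaks$amplitude - (-8)), 2.5)
  expect_true(res$peaks$latency >= 200 && res$peaks$latency <= 400)

  # expected variant uses only the expectation-consistent epochs
  tr2 <- tr; tr2$chose_rich <- rep(c(TRUE, FALSE, FALSE, TRUE), 50)
  ep2 <- synth_epochs(tr2, spec, noise, seed = 92)
  res2 <- frn_analysis(ep2, "expected", channels = "FCz")
  expect_equal(res2$n_minuend, sum(!tr2$chose_rich & tr2$reward == 0))
  expect_equal(res2$n_subtrahend, sum(tr2$chose_rich & tr2$reward == 1))

  # a side below the minimum count is reported missing, not fabricated
  few <- frn_analysis(ep2, "expected", channels = "FCz", min_epochs = 1000)
  expect_true(few$missing)
  expect_null(few$peaks)
})

test_that("pure-noise FRN amplitude matches the extreme-value oracle", {
  # no embedded component: the windowed minimum of the noise-only
  # difference wave has a small negative expectation, not zero
  tr <- data.frame(condition = "neutral", block = 1, trial_in_block = 1:200,
                   reward = rep(c(1, 0), 100),
                   chose_rich = rep(c(TRUE, FALSE), 100))
  spec <- group_spec("NN", frn_amp = c(FCz = 0))
  noise <- eeg_noise_spec(sd = 5, montage = "FCz")
  amps <- vapply(1:12, function(s) {
    ep <- synth_epochs(tr, spec, noise, seed = s)
    frn_analysis(ep, "general", channels = "FCz")$peaks$amplitude
  }, numeric(1))
  # oracle: Monte-Carlo minimum of 201 iid normals at the difference-wave SD
  set.seed(1)
  sd_dw <- 5 * sqrt(2 / 100)
  oracle <- mean(replicate(3000, min(rnorm(201, 0, sd_dw))))
  expect_lt(mean(amps), 0)
  expect_equal(mean(amps), oracle, tolerance = 0.35)
})

test_that("the pipeline is linear: scaling inputs scales amplitudes", {
  tr <- data.frame(condition = "neutral", block = 1, trial_in_block = 1:60,
                   reward = rep(c(1, 0), 30),
                   chose_rich = rep(c(TRUE, FALSE), 30))
  ep <- synth_epochs(tr, group_spec("NN", frn_amp = c(FCz = -6)),
                     eeg_noise_spec(sd = 3, montage = "FCz"), seed = 14)
  ep3 <- ep; ep3$data <- ep$data * 3
  r1 <- frn_analysis(ep, "general", channels = "FCz", min_epochs = 5)
  r3 <- frn_analysis(ep3, "general", channels = "FCz", min_epochs = 5)
  expect_equal(r3$peaks$amplitude, 3 * r1$peaks$amplitude)
  expect_equal(unclass(r3$wave), 3 * unclass(r1$wave))
})

test_that("embedded components are recovered across seeds", {
  # amplitude within 10% and latency within 10 ms when the component is
  # at least 3x the noise SD
  tr <- data.frame(condition = "neutral", block = 1, trial_in_block = 1:800,
                   reward = rep(c(1, 0), 400),
                   chose_rich = rep(c(TRUE, FALSE), 400))
  spec <- group_spec("NN", frn_amp = c(FCz = -9))
  noise <- eeg_noise_spec(sd = 3, montage = "FCz")
  res <- vapply(1:100, function(s) {
    ep <- synth_epochs(tr, spec, noise, seed = 100 + s)
    pk <- frn_analysis(ep, "general", channels = "FCz")$peaks
    c(pk$amplitude, pk$latency)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - (-9)), 0.1 * 9)
  expect_gte(mean(abs(res[1, ] - (-9)) < 0.1 * 9), 0.95)
  expect_gte(mean(abs(res[2, ] - 280) <= 10), 0.95)
})

test_that("re-referencing subtracts the mastoid mean and can be a no-op", {
  sig <- rbind(Fz = rnorm(100), M1 = rnorm(100), M2 = rnorm(100))
  rec <- eeg_record(sig, c("Fz", "M1", "M2"))
  rr <- rereference(rec, c("M1", "M2"))
  expect_equal(rr$signal["Fz", ],
               sig["Fz", ] - colMeans(sig[c("M1", "M2"), ]))
  flat <- eeg_record(rbind(Fz = rnorm(50), M1 = 0, M2 = 0),
                     c("Fz", "M1", "M2"))
  expect_equal(rereference(flat, c("M1", "M2"))$signal, flat$signal)
})
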