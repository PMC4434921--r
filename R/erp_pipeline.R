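#' Construct a continuous EEG record
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param channels Channel names (rows of `signal`).
#' @param rate Sampling rate in Hz.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(signal, channels, rate = 1000) {
  signal <- rbind(signal)
  stopifnot(nrow(signal) == length(channels), rate > 0)
  rownames(signal) <- channels
  structure(list(signal = signal, channels = channels, rate = rate),
            class = "eeg_record")
}

#' Construct a set of EEG epochs
#'
#' @param data 3-way numeric array: epoch x channel x time sample, microvolts.
#' @param channels Channel names.
#' @param rate Sampling rate in Hz.
#' @param window Epoch window in ms relative to the event, `c(start, end)`
#'   with `start < 0 < end`; both endpoints inclusive.
#' @param labels `data.frame` of per-epoch labels (one row per epoch), or
#'   `NULL`.
#' @return An object of class `epoch_set` with a `times` vector in ms.
#' @export
epoch_set <- function(data, channels, rate = 1000,
                      window = c(-100, 700), labels = NULL) {
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == length(channels),
            window[1] < 0, window[2] > 0)
  times <- seq(window[1], window[2], by = 1000 / rate)
  if (abs(length(times) - dim(data)[3]) > 1L)
    stop("sample count inconsistent with window span and rate")
  times <- times[seq_len(dim(data)[3])]
  if (!is.null(labels)) {
    labels <- as.data.frame(labels)
    stopifnot(nrow(labels) == dim(data)[1])
  }
  structure(list(data = data, channels = channels, rate = rate,
                 window = window, times = times, labels = labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("EpochSet:", dim(x$data)[1], "epochs x", length(x$channels),
      "channels x", dim(x$data)[3], "samples (",
      x$window[1], "..", x$window[2], "ms @", x$rate, "Hz )\n")
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs An [epoch_set()].
#' @return Integer epoch count.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]

# subset epochs by logical/integer index, keeping labels aligned
.subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$channels,
            epochs$rate, epochs$window,
            if (!is.null(epochs$labels))
              epochs$labels[idx, , drop = FALSE] else NULL)
}

#' Zero-phase Butterworth bandpass filter
#'
#' A 4th-order Butterworth bandpass applied forward and backward
#' (zero phase). Intended for continuous records before segmentation --- a
#' 0.1 Hz highpass cannot act within a sub-second epoch --- but accepts
#' epoched input for completeness, filtering each epoch and channel
#' independently.
#'
#' @param x An [eeg_record()], [epoch_set()], numeric vector, or
#'   channels x samples matrix.
#' @param low,high Band edges in Hz, `0 < low < high < rate/2`.
#' @param rate Sampling rate in Hz (taken from the object when available).
#' @return The filtered object, same shape and class as the input.
#' @export
bandpass <- function(x, low = 0.1, high = 40, rate = NULL) {
  if (inherits(x, "eeg_record")) rate <- x$rate
  if (inherits(x, "epoch_set")) rate <- x$rate
  if (is.null(rate)) stop("rate is required for plain numeric input")
  if (!(low > 0 && low < high && high < rate / 2))
    stop("band edges must satisfy 0 < low < high < rate/2 (Nyquist)")
  bf <- signal::butter(2, c(low, high) / (rate / 2), type = "pass")
  filt1 <- function(v) signal::filtfilt(bf, v)
  if (inherits(x, "eeg_record")) {
    x$signal <- t(apply(x$signal, 1, filt1))
    rownames(x$signal) <- x$channels
    return(x)
  }
  if (inherits(x, "epoch_set")) {
    x$data <- aperm(apply(x$data, c(1, 2), filt1), c(2, 3, 1))
    return(x)
  }
  if (is.matrix(x)) return(t(apply(x, 1, filt1)))
  filt1(x)
}

#' Re-reference a continuous record to the mean of reference channels
#'
#' Subtracts the mean of the named reference channels (e.g. the two
#' mastoids) from every channel. A no-op when the references are flat, as in
#' reference-free synthetic data.
#'
#' @param record An [eeg_record()].
#' @param ref_channels Names of the reference channels.
#' @return The re-referenced record.
#' @export
rereference <- function(record, ref_channels) {
  stopifnot(inherits(record, "eeg_record"),
            all(ref_channels %in% record$channels))
  ref <- colMeans(record$signal[ref_channels, , drop = FALSE])
  record$signal <- sweep(record$signal, 2, ref)
  record
}

#' Segment a continuous record into event-locked epochs
#'
#' Sample 0 of the record is time 0 ms; an event at `e` ms is the sample
#' nearest `e`, and each epoch spans `window` ms around it, endpoints
#' inclusive. Events whose window would run off either edge of the record
#' are dropped with a warning carrying the count.
#'
#' @param record An [eeg_record()].
#' @param events_ms Event onset times in ms.
#' @param window Epoch window in ms, `c(start, end)`, `start < 0 < end`.
#' @param labels Optional per-event `data.frame`, subset along with the
#'   surviving events.
#' @return An [epoch_set()].
#' @export
epoch_signal <- function(record, events_ms, window = c(-100, 700),
                         labels = NULL) {
  stopifnot(inherits(record, "eeg_record"), window[1] < 0, window[2] > 0)
  rate <- record$rate
  n_samp <- ncol(record$signal)
  i0 <- round(events_ms * rate / 1000) + 1L
  off <- round(window * rate / 1000)
  keep <- i0 + off[1] >= 1L & i0 + off[2] <= n_samp
  if (any(!keep))
    warning(sum(!keep), " event(s) too close to the record edge; dropped")
  if (!sum(keep)) stop("no events remain within the record bounds")
  i0 <- i0[keep]
  rel <- off[1]:off[2]
  data <- array(NA_real_, c(length(i0), length(record$channels), length(rel)))
  for (k in seq_along(i0))
    data[k, , ] <- record$signal[, i0[k] + rel, drop = FALSE]
  if (!is.null(labels)) labels <- labels[keep, , drop = FALSE]
  epoch_set(data, record$channels, rate, window, labels)
}

#' Baseline-correct epochs to the pre-stimulus mean
#'
#' Per epoch and channel, subtracts the mean over the pre-stimulus samples
#' (`[window start, 0)` ms), so the pre-stimulus mean of the output is zero.
#'
#' @param epochs An [epoch_set()].
#' @return The corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  pre <- epochs$times < 0
  if (!any(pre)) stop("no pre-stimulus samples to baseline on")
  bl <- apply(epochs$data[, , pre, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over time dimension
  epochs
}

#' Amplitude-threshold artifact rejection
#'
#' Removes every epoch in which any channel at any sample exceeds
#' `±threshold` microvolts (strictly greater in absolute value).
#'
#' @param epochs An [epoch_set()].
#' @param threshold Rejection threshold in microvolts (> 0).
#' @param by Optional label column over whose levels per-level rejection
#'   rates are reported.
#' @return A list: `epochs` (the kept set), `report` with totals, overall
#'   rate, per-level rates, and `all_rejected` flag.
#' @export
reject_artifacts <- function(epochs, threshold = 50, by = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), threshold > 0)
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= threshold
  per_level <- NULL
  if (!is.null(by) && !is.null(epochs$labels) && by %in% names(epochs$labels)) {
    lv <- as.character(epochs$labels[[by]])
    per_level <- tapply(!keep, lv, mean)
  }
  report <- list(n_total = length(keep), n_rejected = sum(!keep),
                 rate = mean(!keep), threshold = threshold,
                 per_level = per_level, all_rejected = !any(keep))
  if (!any(keep))
    return(list(epochs = .subset_epochs(epochs, keep), report = report))
  list(epochs = .subset_epochs(epochs, keep), report = report)
}

#' Classify feedback outcomes by expectation
#'
#' An outcome is *expected* when choosing the rich deck delivers reward or
#' choosing the poor deck omits it, and *unexpected* otherwise:
#' rich+reward = expected-delivery, poor+no-reward = expected-omission,
#' poor+reward = unexpected-delivery, rich+no-reward = unexpected-omission.
#'
#' @param trials Trial log with columns `reward` and either `chose_rich` or
#'   (`choice` plus `rich_deck`).
#' @param schedule Optional [generate_schedule()] used to resolve the rich
#'   deck when the log lacks it.
#' @return Factor of outcome classes, one per trial.
#' @export
classify_outcome <- function(trials, schedule = NULL) {
  if (!"chose_rich" %in% names(trials)) {
    if (!"rich_deck" %in% names(trials)) {
      stopifnot(!is.null(schedule))
      trials$rich_deck <- vapply(trials$trial, function(t)
        label_rich_deck(schedule, t), character(1))
    }
    trials$chose_rich <- trials$choice == trials$rich_deck
  }
  rewarded <- trials$reward == 1
  cls <- ifelse(trials$chose_rich & rewarded, "expected-delivery",
         ifelse(!trials$chose_rich & !rewarded, "expected-omission",
         ifelse(!trials$chose_rich & rewarded, "unexpected-delivery",
                "unexpected-omission")))
  factor(cls, levels = .outcome_levels)
}

#' Average epochs into an ERP
#'
#' @param epochs An [epoch_set()].
#' @param which Logical or integer selection of epochs (default all).
#' @return A channels x time matrix of class `erp_average` with `times`,
#'   `rate` and `n_epochs` attributes.
#' @export
average_epochs <- function(epochs, which = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(which)) which <- seq_len(n_epochs(epochs))
  if (is.logical(which)) which <- which(which)
  if (!length(which)) stop("refusing to average an empty epoch selection")
  m <- apply(epochs$data[which, , , drop = FALSE], c(2, 3), mean)
  rownames(m) <- epochs$channels
  structure(m, class = "erp_average", times = epochs$times,
            rate = epochs$rate, n_epochs = length(which))
}

#' Pointwise difference of two averaged ERPs
#'
#' By the FRN convention the minuend is the omission/non-reward average and
#' the subtrahend the delivery/reward average.
#'
#' @param minuend,subtrahend `erp_average` matrices with matching channels
#'   and time axes.
#' @return A channels x time `erp_average` difference wave; the `n_epochs`
#'   attribute holds both contributing counts.
#' @export
difference_wave <- function(minuend, subtrahend) {
  if (!identical(rownames(minuend), rownames(subtrahend)) ||
      !isTRUE(all.equal(attr(minuend, "times"), attr(subtrahend, "times"))))
    stop("operands differ in channels or time axis")
  structure(unclass(minuend) - unclass(subtrahend), class = "erp_average",
            times = attr(minuend, "times"), rate = attr(minuend, "rate"),
            n_epochs = c(minuend = attr(minuend, "n_epochs"),
                         subtrahend = attr(subtrahend, "n_epochs")))
}

#' Windowed peak amplitude and latency
#'
#' The most negative (or positive) sample within the search window, per
#' channel; ties are broken toward the earliest latency.
#'
#' @param wave An `erp_average` (possibly a difference wave).
#' @param window Search window in ms, e.g. `c(200, 400)` for the FRN.
#' @param polarity `"negative"` or `"positive"`.
#' @return A `data.frame`: channel, amplitude (microvolts), latency (ms).
#' @export
peak_component <- function(wave, window, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  times <- attr(wave, "times")
  sel <- which(times >= window[1] & times <= window[2])
  if (!length(sel)) stop("empty search window")
  m <- unclass(wave)[, sel, drop = FALSE]
  idx <- apply(if (polarity == "negative") m else -m, 1, which.min)
  data.frame(channel = rownames(wave),
             amplitude = m[cbind(seq_len(nrow(m)), idx)],
             latency = times[sel][idx],
             row.names = NULL, stringsAsFactors = FALSE)
}

.outcome_levels <- c("expected-delivery", "expected-omission",
                     "unexpected-delivery", "unexpected-omission")

# the two label sets contrasted by each FRN variant
.frn_sides <- function(variant) {
  switch(variant,
    general = list(minuend = c("expected-omission", "unexpected-omission"),
                   subtrahend = c("expected-delivery", "unexpected-delivery")),
    expected = list(minuend = "expected-omission",
                    subtrahend = "expected-delivery"),
    unexpected = list(minuend = "unexpected-omission",
                      subtrahend = "unexpected-delivery"))
}

#' FRN difference-wave analysis
#'
#' Averages the two sides of the requested variant (General: all non-reward
#' vs all reward; Expected: expected-omission vs expected-delivery;
#' Unexpected: unexpected-omission vs unexpected-delivery), forms the
#' difference wave, and extracts the windowed negative peak at the requested
#' channels. Epochs must carry an `outcome_class` label (see
#' [classify_outcome()]).
#'
#' @param epochs A labeled [epoch_set()].
#' @param variant `"general"`, `"expected"` or `"unexpected"`.
#' @param channels Channels at which peaks are measured.
#' @param window Peak search window in ms.
#' @param min_epochs Minimum epochs required on each side; below it the cell
#'   is returned as missing rather than fabricated.
#' @param split_by Optional label column; the analysis is run per level and
#'   a named list returned.
#' @return An object of class `frn_result` (or a named list of them when
#'   `split_by` is used): difference `wave`, `peaks` table, `variant`,
#'   epoch counts per side, and `missing` flag.
#' @export
frn_analysis <- function(epochs, variant = c("general", "expected",
                                             "unexpected"),
                         channels = c("Fz", "FCz", "Cz"),
                         window = c(200, 400), min_epochs = 10,
                         split_by = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(epochs, "epoch_set"),
            !is.null(epochs$labels), "outcome_class" %in% names(epochs$labels))
  if (!all(channels %in% epochs$channels))
    stop("requested channels missing from the montage")
  if (!is.null(split_by)) {
    stopifnot(split_by %in% names(epochs$labels))
    lv <- as.character(epochs$labels[[split_by]])
    res <- lapply(unique(lv), function(l)
      frn_analysis(.subset_epochs(epochs, lv == l), variant, channels,
                   window, min_epochs))
    names(res) <- unique(lv)
    return(res)
  }
  sides <- .frn_sides(variant)
  cls <- as.character(epochs$labels$outcome_class)
  i_min <- cls %in% sides$minuend
  i_sub <- cls %in% sides$subtrahend
  n_min <- sum(i_min); n_sub <- sum(i_sub)
  if (n_min < min_epochs || n_sub < min_epochs) {
    return(structure(list(variant = variant, wave = NULL, peaks = NULL,
                          n_minuend = n_min, n_subtrahend = n_sub,
                          window = window, missing = TRUE),
                     class = "frn_result"))
  }
  chan_idx <- match(channels, epochs$channels)
  sub <- epoch_set(epochs$data[, chan_idx, , drop = FALSE],
                   channels, epochs$rate, epochs$window, epochs$labels)
  dw <- difference_wave(average_epochs(sub, i_min), average_epochs(sub, i_sub))
  structure(list(variant = variant, wave = dw,
                 peaks = peak_component(dw, window, "negative"),
                 n_minuend = n_min, n_subtrahend = n_sub,
                 window = window, missing = FALSE),
            class = "frn_result")
}

#' @export
print.frn_result <- function(x, ...) {
  lab <- paste0(toupper(substring(x$variant, 1, 1)), substring(x$variant, 2))
  cat(sprintf("%s FRN (%d vs %d epochs, %d..%d ms)\n",
              lab, x$n_minuend, x$n_subtrahend, x$window[1], x$window[2]))
  if (x$missing) cat("  cell missing: side below minimum epoch count\n")
  else print(x$peaks)
  invisible(x)
}
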