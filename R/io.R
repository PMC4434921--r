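#' Write and read trial logs as TSV
#'
#' The trial-log interchange format: one row per trial with columns subject,
#' trial, condition, pair, choice, reward, q1, q2, p_choice, delta (extra
#' columns are preserved).
#'
#' @param trials A trial log `data.frame` (or a list of per-subject logs,
#'   which is row-bound).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  if (is.list(trials) && !is.data.frame(trials))
    trials <- do.call(rbind, trials)
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Export a schedule and reward realization as TSV plus a JSON sidecar
#'
#' One row per trial (trial, condition, pair, deck probabilities, rich deck
#' and, when a realization is given, the pre-drawn outcomes), with the
#' configuration and seeds in `<path>.json`.
#'
#' @param schedule A [generate_schedule()] result.
#' @param path Output TSV path.
#' @param rewards Optional matching [realize_rewards()] result.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path, rewards = NULL) {
  stopifnot(inherits(schedule, "task_schedule"))
  tab <- schedule$trials
  if (!is.null(rewards)) {
    stopifnot(nrow(rewards$outcomes) == nrow(tab))
    tab$outcome1 <- rewards$outcomes[, 1]
    tab$outcome2 <- rewards$outcomes[, 2]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(config = unclass(schedule$config),
               seed = schedule$seed,
               reward_seed = if (!is.null(rewards)) rewards$seed else NULL,
               pair_of_condition = as.list(schedule$pair_of_condition))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write and read an epoch bundle
#'
#' The bundle is a directory holding `meta.json` (channels, sampling rate,
#' window in ms, per-epoch label table) and `epochs.bin` (little-endian
#' 32-bit floats, epoch-major, then channel, then time sample).
#'
#' @param epochs An [epoch_set()].
#' @param dir Bundle directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epoch_bundle <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(channels = epochs$channels, rate = epochs$rate,
               window_ms = epochs$window, n_epochs = dim(epochs$data)[1],
               n_samples = dim(epochs$data)[3], labels = epochs$labels)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  con <- file(file.path(dir, "epochs.bin"), "wb")
  on.exit(close(con))
  # epoch-major: for each epoch, channels in order, each a full time series
  writeBin(as.vector(aperm(epochs$data, c(3, 2, 1))), con,
           size = 4L, endian = "little")
  invisible(dir)
}

#' @rdname write_epoch_bundle
#' @export
read_epoch_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  n <- meta$n_epochs * length(meta$channels) * meta$n_samples
  raw <- readBin(file.path(dir, "epochs.bin"), "numeric", n = n, size = 4L,
                 endian = "little")
  data <- aperm(array(raw, c(meta$n_samples, length(meta$channels),
                             meta$n_epochs)), c(3, 2, 1))
  labels <- if (!is.null(meta$labels)) as.data.frame(meta$labels) else NULL
  if (!is.null(labels) && "outcome_class" %in% names(labels))
    labels$outcome_class <- factor(labels$outcome_class,
                                   levels = .outcome_levels)
  epoch_set(data, meta$channels, meta$rate, unlist(meta$window_ms), labels)
}
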