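#' Construct an epoched single-trial EEG set
#'
#' The central data container: a subject's epoched single-trial EEG with
#' condition labels, validity flags and chronological trial indices. Epochs
#' share one half-open time grid \code{[epoch_start, epoch_end)} with samples
#' at the left edge of each sampling interval, so the sample count is
#' \code{round((epoch_end - epoch_start) * sampling_rate / 1000)}.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param sampling_rate Sampling rate in Hz.
#' @param channels Character vector of channel names, in recording order.
#' @param trials Data frame with columns \code{chrono_index} (unique positive
#'   integers giving experiment order), \code{condition} (character) and
#'   \code{valid} (logical; invalid trials are excluded from every average and
#'   resample).
#' @param data Numeric array of dimension \code{n_trials x n_channels x
#'   n_samples}, amplitudes in microvolts.
#' @param epoch_start,epoch_end Epoch extent in ms relative to stimulus onset;
#'   the default \code{[-100, 1000)} ms window brackets the P3 complex.
#' @param conditions Declared condition label set; defaults to the labels
#'   present in \code{trials}.
#'
#' @return An object of class \code{"epoch_set"}: a list with the fields
#'   above plus \code{times}, the ms grid.
#' @export
epoch_set <- function(subject_id, sampling_rate, channels, trials, data,
                      epoch_start = -100, epoch_end = 1000,
                      conditions = NULL) {
  es <- structure(list(
    subject_id = as.character(subject_id),
    sampling_rate = as.numeric(sampling_rate),
    epoch_start = as.numeric(epoch_start),
    epoch_end = as.numeric(epoch_end),
    channels = as.character(channels),
    conditions = if (is.null(conditions)) sort(unique(as.character(trials$condition))) else as.character(conditions),
    trials = as.data.frame(trials),
    data = data
  ), class = "epoch_set")
  es$times <- epoch_time_grid(es$epoch_start, es$epoch_end, es$sampling_rate)
  validate_epoch_set(es)
  es
}

#' @rdname epoch_set
#' @param start,end Window edges in ms (half-open).
#' @export
epoch_time_grid <- function(start, end, sampling_rate) {
  n <- round((end - start) * sampling_rate / 1000)
  start + (seq_len(n) - 1) * 1000 / sampling_rate
}

validate_epoch_set <- function(es) {
  stopifnot(is.character(es$channels), length(es$channels) >= 1)
  n_samp <- round((es$epoch_end - es$epoch_start) * es$sampling_rate / 1000)
  if (!is.array(es$data) || length(dim(es$data)) != 3)
    stop("data must be a trials x channels x samples array")
  d <- dim(es$data)
  if (d[1] != nrow(es$trials))
    stop("data has ", d[1], " trials but trial table has ", nrow(es$trials))
  if (d[2] != length(es$channels))
    stop("data has ", d[2], " channels but channel list has ", length(es$channels))
  if (d[3] != n_samp)
    stop("data has ", d[3], " samples; grid requires ", n_samp)
  if (!all(is.finite(es$data))) stop("non-finite amplitudes in data")
  ci <- es$trials$chrono_index
  if (anyDuplicated(ci) || any(ci < 1) || any(ci != round(ci)))
    stop("chrono_index must be unique positive integers")
  if (!all(es$trials$condition %in% es$conditions))
    stop("condition label outside declared set: ",
         paste(setdiff(es$trials$condition, es$conditions), collapse = ", "))
  invisible(es)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("Epoch set: subject", x$subject_id, "\n")
  cat(sprintf("  %d trials, %d channels (%s), %d samples @ %g Hz, [%g, %g) ms\n",
              nrow(x$trials), length(x$channels),
              paste(x$channels, collapse = ", "),
              dim(x$data)[3], x$sampling_rate, x$epoch_start, x$epoch_end))
  tab <- table(condition = x$trials$condition, valid = x$trials$valid)
  print(tab)
  invisible(x)
}

#' Subset an epoch set by trial
#'
#' @param es An \code{epoch_set}.
#' @param idx Integer or logical index into the trial table.
#' @return An \code{epoch_set} holding only the selected trials.
#' @export
subset_trials <- function(es, idx) {
  es$trials <- es$trials[idx, , drop = FALSE]
  rownames(es$trials) <- NULL
  es$data <- es$data[idx, , , drop = FALSE]
  es
}

#' Count valid trials per condition
#'
#' @param es An \code{epoch_set}.
#' @return Named integer vector of valid-trial counts, one per declared
#'   condition.
#' @export
valid_counts <- function(es) {
  vapply(es$conditions, function(cc)
    sum(es$trials$condition == cc & es$trials$valid), integer(1))
}

# Indices of valid trials of one condition, in table order
valid_idx <- function(es, condition) {
  which(es$trials$condition == condition & es$trials$valid)
}

# trials x samples matrix for one channel / condition (valid trials only)
condition_matrix <- function(es, condition, channel) {
  i <- valid_idx(es, condition)
  ch <- match(channel, es$channels)
  if (is.na(ch)) stop("unknown channel: ", channel)
  m <- es$data[i, ch, , drop = FALSE]
  dim(m) <- c(length(i), dim(es$data)[3])
  m
}
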