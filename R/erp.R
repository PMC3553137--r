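#' Construct a waveform (one channel's time series)
#'
#' @param channel Channel name.
#' @param times Strictly increasing ms grid with uniform step.
#' @param values Amplitudes in microvolts, one per time point.
#' @param n_trials Number of trials contributing (0 for bookkeeping objects
#'   such as raw difference waves).
#' @return An object of class \code{"waveform"}.
#' @export
waveform <- function(channel, times, values, n_trials = 0L) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6)
    stop("times must be strictly increasing with uniform step")
  structure(list(channel = channel, times = as.numeric(times),
                 values = as.numeric(values), n_trials = as.integer(n_trials)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform %s: %d samples [%g, %g] ms, %d trials, range [%.3g, %.3g] uV\n",
              x$channel, length(x$times), min(x$times), max(x$times),
              x$n_trials, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.waveform <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "time (ms)",
       ylab = expression(paste("amplitude (", mu, "V)")),
       main = x$channel, ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Average the valid trials of one condition into an ERP
#'
#' @param es An \code{\link{epoch_set}}.
#' @param condition Condition label.
#' @param channel Channel name.
#' @return A \code{\link{waveform}} with \code{n_trials} set to the number of
#'   valid trials averaged.
#' @export
average_erp <- function(es, condition, channel) {
  m <- condition_matrix(es, condition, channel)
  if (nrow(m) == 0) stop("no valid trials of condition ", condition)
  waveform(channel, es$times, colMeans(m), n_trials = nrow(m))
}

#' Pointwise difference of two waveforms (a minus b)
#'
#' The basis of every contrast: the condition-minus-baseline difference wave
#' on which peak-to-peak statistics are computed.
#'
#' @param a,b \code{\link{waveform}}s on identical time grids and channel.
#' @return A \code{\link{waveform}}; \code{n_trials} is 0 (bookkeeping only).
#' @export
difference_wave <- function(a, b) {
  if (length(a$times) != length(b$times) ||
      max(abs(a$times - b$times)) > 1e-9)
    stop("time grid mismatch")
  if (!identical(a$channel, b$channel))
    stop("channel mismatch: ", a$channel, " vs ", b$channel)
  waveform(a$channel, a$times, a$values - b$values, n_trials = 0L)
}

#' Pool trials across subjects and average (fixed effects)
#'
#' Unweighted mean over every pooled valid trial, so subjects with more valid
#' trials weigh more — a fixed-effects grand average, as used by the pooled
#' latency contrast.
#'
#' @param subjects A single \code{\link{epoch_set}} or a list of them, sharing
#'   grid and channels.
#' @param condition Condition label pooled from every subject.
#' @param channel Channel name.
#' @return A \code{\link{waveform}} with \code{n_trials} the pooled count.
#' @export
pooled_average <- function(subjects, condition, channel) {
  if (inherits(subjects, "epoch_set")) subjects <- list(subjects)
  mats <- lapply(subjects, condition_matrix, condition = condition, channel = channel)
  pool <- do.call(rbind, mats)
  if (is.null(pool) || nrow(pool) == 0) stop("empty pool for condition ", condition)
  waveform(channel, subjects[[1]]$times, colMeans(pool), n_trials = nrow(pool))
}

# trials x samples pool matrix across subjects, with times attribute
pool_matrix <- function(subjects, condition, channel) {
  if (inherits(subjects, "epoch_set")) subjects <- list(subjects)
  pool <- do.call(rbind, lapply(subjects, condition_matrix,
                                condition = condition, channel = channel))
  attr(pool, "times") <- subjects[[1]]$times
  pool
}
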