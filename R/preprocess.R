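#' Baseline-correct every trial
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window from every sample. The default window is the 100 ms of pre-stimulus
#' activity, \code{[-100, 0)} ms.
#'
#' @param es An \code{\link{epoch_set}}.
#' @param window Length-2 numeric, baseline window \code{c(start, end)} in ms,
#'   half-open on the right; must lie within the epoch extent.
#' @return The corrected \code{epoch_set}.
#' @export
baseline_correct <- function(es, window = c(-100, 0)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (window[1] < es$epoch_start - 1e-9 || window[2] > es$epoch_end + 1e-9)
    stop("baseline window [", window[1], ", ", window[2],
         ") outside epoch extent")
  idx <- which(es$times >= window[1] - 1e-9 & es$times < window[2] - 1e-9)
  if (!length(idx)) stop("baseline window contains no samples")
  bl <- apply(es$data[, , idx, drop = FALSE], c(1, 2), mean)
  es$data <- es$data - as.vector(bl)  # recycles over samples (3rd dim)
  es
}

#' Flag trials exceeding an amplitude threshold as invalid
#'
#' A trial is rejected (marked \code{valid = FALSE}) when any sample on any
#' analysed channel is strictly above \code{+threshold} or strictly below
#' \code{-threshold} microvolts; a sample at exactly the threshold is kept.
#' Already-invalid trials stay invalid, so the operation is idempotent.
#'
#' @param es An \code{\link{epoch_set}}.
#' @param threshold Positive rejection threshold in microvolts (default 50).
#' @param channels Channels inspected; defaults to the analysis montage
#'   Fz/Cz/Pz (intersected with the recorded channels), falling back to all
#'   channels when none of those are present.
#' @return The \code{epoch_set} with updated validity flags and an attribute
#'   \code{"n_valid"} holding post-rejection valid counts per condition (also
#'   available via \code{\link{valid_counts}}).
#' @export
reject_amplitude <- function(es, threshold = 50,
                             channels = intersect(es$channels, c("Fz", "Cz", "Pz"))) {
  stopifnot(threshold > 0)
  if (!length(channels)) channels <- es$channels
  ch <- match(channels, es$channels)
  if (anyNA(ch)) stop("unknown channel(s): ",
                      paste(channels[is.na(ch)], collapse = ", "))
  sub <- es$data[, ch, , drop = FALSE]
  exceed <- apply(abs(sub) > threshold, 1, any)
  es$trials$valid <- es$trials$valid & !exceed
  attr(es, "n_valid") <- valid_counts(es)
  es
}

#' Split one condition's valid trials into chronological halves
#'
#' Valid trials of \code{condition}, ordered by chronological index, are split
#' into an early half (the first \code{ceiling(n/2)} trials) and a late half
#' (the remainder). Used for the early-vs-late repetition control.
#'
#' @param es An \code{\link{epoch_set}}.
#' @param condition Condition label to split.
#' @return \code{list(early = , late = )} of \code{epoch_set}s.
#' @export
split_half_chronological <- function(es, condition) {
  i <- valid_idx(es, condition)
  if (length(i) < 2) stop("need at least 2 valid trials of ", condition)
  i <- i[order(es$trials$chrono_index[i])]
  n_early <- ceiling(length(i) / 2)
  list(early = subset_trials(es, i[seq_len(n_early)]),
       late = subset_trials(es, i[-seq_len(n_early)]))
}

#' Split one condition's valid trials by within-condition parity
#'
#' Valid trials of \code{condition} are ranked 1, 2, 3, ... by chronological
#' index within the condition; odd ranks form the odd set and even ranks the
#' even set. Parity is of the rank, not of the raw chronological index, so
#' gaps left by other conditions or rejected trials do not matter.
#'
#' @inheritParams split_half_chronological
#' @return \code{list(odd = , even = )} of \code{epoch_set}s.
#' @export
split_parity <- function(es, condition) {
  i <- valid_idx(es, condition)
  if (length(i) < 2) stop("need at least 2 valid trials of ", condition)
  i <- i[order(es$trials$chrono_index[i])]
  rk <- seq_along(i)
  list(odd = subset_trials(es, i[rk %% 2 == 1]),
       even = subset_trials(es, i[rk %% 2 == 0]))
}
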