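#' Peak-measurement parameters
#'
#' A "peak" is never a single time point but the mean amplitude over a short
#' inner window slid across a bounding window. \code{peak_params} configures
#' the biphasic peak-to-peak statistic; \code{latency_params} the
#' windowed-maximum latency statistic.
#'
#' Presets (obtained via \code{peak_preset}):
#' \describe{
#'   \item{\code{"p3b"}}{bounding 300-1000 ms, inner 100 ms, no cap — the
#'     broad parietal positivity, maximal at Pz.}
#'   \item{\code{"p3a"}}{bounding 150-1000 ms, inner 100 ms, highest-peak
#'     search capped so that the inner window ends by 300 ms — the early
#'     fronto-central component at Fz/Cz. The cap stops the later P3b from
#'     being picked up as the P3a's positive peak, which also means a P3a
#'     peak-to-peak value can be negative.}
#'   \item{\code{"p3a-latency"}}{bounding 150-400 ms, inner 50 ms.}
#'   \item{\code{"p3b-latency"}}{bounding 300-1000 ms, inner 100 ms.}
#' }
#'
#' @param bound_start,bound_end Bounding window in ms (half-open).
#' @param inner Inner-window width in ms.
#' @param high_limit Optional cap (ms): the highest-peak inner window must end
#'   at or before this time. \code{NULL} for no cap.
#' @return A list of class \code{"peak_params"} / \code{"latency_params"}.
#' @export
peak_params <- function(bound_start, bound_end, inner, high_limit = NULL) {
  stopifnot(bound_start < bound_end, inner > 0, inner <= bound_end - bound_start)
  if (!is.null(high_limit))
    stopifnot(high_limit > bound_start, high_limit <= bound_end)
  structure(list(bound_start = bound_start, bound_end = bound_end,
                 inner = inner, high_limit = high_limit),
            class = "peak_params")
}

#' @rdname peak_params
#' @export
latency_params <- function(bound_start, bound_end, inner) {
  p <- peak_params(bound_start, bound_end, inner)
  class(p) <- "latency_params"
  p
}

#' @rdname peak_params
#' @param name One of \code{"p3a"}, \code{"p3b"}, \code{"p3a-latency"},
#'   \code{"p3b-latency"}.
#' @export
peak_preset <- function(name) {
  switch(name,
         "p3b" = peak_params(300, 1000, 100),
         "p3a" = peak_params(150, 1000, 100, high_limit = 300),
         "p3a-latency" = latency_params(150, 400, 50),
         "p3b-latency" = latency_params(300, 1000, 100),
         stop("unknown preset: ", name))
}

# Default electrode -> parameter mapping of the individual-level analysis
default_channel_params <- function(channels = c("Fz", "Cz", "Pz")) {
  presets <- ifelse(channels == "Pz", "p3b", "p3a")
  stats::setNames(lapply(presets, peak_preset), channels)
}

# Start indices (into the sample grid) of inner windows lying wholly within
# [lo, hi). L = window length in samples. Returns integer(0) if none fit.
window_starts <- function(times, inner, lo, hi) {
  eps <- 1e-9
  which(times >= lo - eps & times + inner <= hi + eps)
}

inner_samples <- function(inner, sampling_rate) {
  L <- round(inner * sampling_rate / 1000)
  if (L < 1) stop("inner window shorter than one sample")
  L
}

#' Sliding inner-window means
#'
#' Means of every sample-aligned inner window \code{[start, start + inner)}
#' lying wholly inside \code{range}; window starts advance one sample at a
#' time.
#'
#' @param w A \code{\link{waveform}}.
#' @param inner Inner-window width in ms.
#' @param range Length-2 numeric \code{c(lo, hi)}, half-open search range in ms.
#' @return Data frame with columns \code{start_ms} and \code{mean_uv}, one row
#'   per admissible start position.
#' @export
sliding_means <- function(w, inner, range) {
  fs <- 1000 / (w$times[2] - w$times[1])
  L <- inner_samples(inner, fs)
  starts <- window_starts(w$times, inner, range[1], range[2])
  if (!length(starts)) stop("no full inner window fits in [",
                            range[1], ", ", range[2], ")")
  cs <- cumsum(c(0, w$values))
  means <- (cs[starts + L] - cs[starts]) / L
  data.frame(start_ms = w$times[starts], mean_uv = means)
}

# Row-wise sliding means for a matrix of waves (rows x samples).
# Returns list(starts = sample indices, means = rows x starts matrix).
sliding_means_matrix <- function(M, times, inner, lo, hi) {
  fs <- 1000 / (times[2] - times[1])
  L <- inner_samples(inner, fs)
  starts <- window_starts(times, inner, lo, hi)
  if (!length(starts)) return(list(starts = integer(0), means = NULL, L = L))
  cs <- cbind(0, t(apply(M, 1, cumsum)))
  means <- (cs[, starts + L, drop = FALSE] - cs[, starts, drop = FALSE]) / L
  list(starts = starts, means = means, L = L)
}

#' Peak-to-peak amplitude of a difference wave
#'
#' Finds the inner window with the highest mean (the positive peak) over the
#' bounding window — capped at \code{high_limit} when set — then searches from
#' the first non-overlapping position after it for the inner window with the
#' lowest mean (the following negative peak). The statistic is highest minus
#' lowest. Ties are broken towards the earliest start. If no full inner
#' window fits after the highest peak the result is degenerate with
#' \code{p2p = 0} (no biphasic component can be claimed).
#'
#' @param w A \code{\link{waveform}} (typically a condition-minus-baseline
#'   difference wave).
#' @param p A \code{\link{peak_params}} object.
#' @return A list of class \code{"p2p_result"}: \code{high_value},
#'   \code{high_start}, \code{low_value}, \code{low_start}, \code{p2p}
#'   (microvolts), \code{degenerate}.
#' @export
peak_to_peak <- function(w, p) {
  stopifnot(inherits(p, "peak_params"))
  fs <- 1000 / (w$times[2] - w$times[1])
  L <- inner_samples(p$inner, fs)
  hi_end <- if (is.null(p$high_limit)) p$bound_end else p$high_limit
  hstarts <- window_starts(w$times, p$inner, p$bound_start, hi_end)
  if (!length(hstarts)) stop("no full inner window fits in the high-peak range")
  cs <- cumsum(c(0, w$values))
  hmeans <- (cs[hstarts + L] - cs[hstarts]) / L
  hb <- which.max(hmeans)  # earliest on ties
  high_value <- hmeans[hb]
  high_start <- w$times[hstarts[hb]]

  all_starts <- window_starts(w$times, p$inner, p$bound_start, p$bound_end)
  lstarts <- all_starts[all_starts >= hstarts[hb] + L]
  if (!length(lstarts)) {
    return(structure(list(high_value = high_value, high_start = high_start,
                          low_value = NA_real_, low_start = NA_real_,
                          p2p = 0, degenerate = TRUE), class = "p2p_result"))
  }
  lmeans <- (cs[lstarts + L] - cs[lstarts]) / L
  lb <- which.min(lmeans)
  structure(list(high_value = high_value, high_start = high_start,
                 low_value = lmeans[lb], low_start = w$times[lstarts[lb]],
                 p2p = high_value - lmeans[lb], degenerate = FALSE),
            class = "p2p_result")
}

#' @export
print.p2p_result <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("Peak-to-peak: degenerate (high %.3f uV @ %g ms, no room for low peak); p2p = 0\n",
                x$high_value, x$high_start))
  else
    cat(sprintf("Peak-to-peak: %.3f uV (high %.3f @ %g ms, low %.3f @ %g ms)\n",
                x$p2p, x$high_value, x$high_start, x$low_value, x$low_start))
  invisible(x)
}

# Vectorised p2p over rows of a wave matrix; returns numeric vector.
# Same algorithm as peak_to_peak(); the two are cross-checked in the tests.
peak_to_peak_matrix <- function(M, times, p) {
  fs <- 1000 / (times[2] - times[1])
  L <- inner_samples(p$inner, fs)
  hi_end <- if (is.null(p$high_limit)) p$bound_end else p$high_limit
  hstarts <- window_starts(times, p$inner, p$bound_start, hi_end)
  astarts <- window_starts(times, p$inner, p$bound_start, p$bound_end)
  if (!length(hstarts)) stop("no full inner window fits in the high-peak range")
  cs <- cbind(0, t(apply(M, 1, cumsum)))
  all_means <- (cs[, astarts + L, drop = FALSE] - cs[, astarts, drop = FALSE]) / L
  n_high <- length(hstarts)  # hstarts is a prefix of astarts
  hmeans <- all_means[, seq_len(n_high), drop = FALSE]
  hb <- max.col(hmeans, ties.method = "first")
  out <- numeric(nrow(M))
  for (r in seq_len(nrow(M))) {
    first_low <- hb[r] + L  # first start not overlapping the high window
    if (first_low > length(astarts)) { out[r] <- 0; next }
    out[r] <- hmeans[r, hb[r]] - min(all_means[r, first_low:length(astarts)])
  }
  out
}

#' Windowed-maximum latency of a waveform
#'
#' Slides the inner window across the bounding range and returns the start
#' (ms) of the placement with the maximal mean amplitude; ties go to the
#' earliest start.
#'
#' @param w A \code{\link{waveform}} (typically a grand average).
#' @param p A \code{\link{latency_params}} object.
#' @return Latency in ms.
#' @export
latency <- function(w, p) {
  stopifnot(inherits(p, "latency_params"))
  sm <- sliding_means(w, p$inner, c(p$bound_start, p$bound_end))
  sm$start_ms[which.max(sm$mean_uv)]
}

# Vectorised latency over rows of a wave matrix
latency_matrix <- function(M, times, p) {
  sm <- sliding_means_matrix(M, times, p$inner, p$bound_start, p$bound_end)
  if (!length(sm$starts)) stop("no full inner window fits in the latency range")
  times[sm$starts[max.col(sm$means, ties.method = "first")]]
}
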