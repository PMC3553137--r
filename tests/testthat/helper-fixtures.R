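# Shared builders for small in-code fixtures.

# Epoch set from a named list: condition -> trials x channels x samples array.
# Chronological indices run in block order unless chrono is supplied.
make_es <- function(cond_arrays, channels, fs = 100, start = 0, end = NULL,
                    subject = "T1", chrono = NULL, valid = NULL) {
  n_samp <- dim(cond_arrays[[1]])[3]
  if (is.null(end)) end <- start + n_samp * 1000 / fs
  data <- do.call(abind3, cond_arrays)
  n_tr <- dim(data)[1]
  trials <- data.frame(
    chrono_index = if (is.null(chrono)) seq_len(n_tr) else chrono,
    condition = rep(names(cond_arrays),
                    vapply(cond_arrays, function(a) dim(a)[1], integer(1))),
    valid = if (is.null(valid)) TRUE else valid)
  epoch_set(subject, fs, channels, trials, data,
            epoch_start = start, epoch_end = end)
}

# bind 3-d arrays along the first (trial) dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, c(n, d[2], d[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# trials x channels x samples array of iid normal noise
noise_array <- function(n_trials, n_ch, n_samp, sd = 1) {
  array(rnorm(n_trials * n_ch * n_samp, sd = sd), c(n_trials, n_ch, n_samp))
}

# constant-amplitude array
const_array <- function(n_trials, n_ch, n_samp, value) {
  array(value, c(n_trials, n_ch, n_samp))
}

# boxcar waveform: `amp` on [lo, hi), 0 elsewhere
boxcar_wave <- function(times, lo, hi, amp, channel = "Pz") {
  v <- numeric(length(times))
  v[times >= lo & times < hi] <- amp
  waveform(channel, times, v)
}

# Independent O(n^2) exhaustive-scan oracle for the peak-to-peak statistic:
# direct mean() over every admissible window, no shared code with the package.
p2p_oracle <- function(values, times, bound_start, bound_end, inner,
                       high_limit = NULL) {
  fs <- 1000 / (times[2] - times[1])
  L <- round(inner * fs / 1000)
  n <- length(values)
  win_mean <- function(i) mean(values[i:(i + L - 1)])
  ok <- function(i, lo, hi) times[i] >= lo - 1e-9 &&
    i + L - 1 <= n && times[i] + inner <= hi + 1e-9
  hi_end <- if (is.null(high_limit)) bound_end else high_limit
  hcand <- Filter(function(i) ok(i, bound_start, hi_end), seq_len(n))
  hmeans <- vapply(hcand, win_mean, numeric(1))
  hb <- hcand[which.max(hmeans)]
  high <- max(hmeans)
  lcand <- Filter(function(i) i >= hb + L && ok(i, bound_start, bound_end),
                  seq_len(n))
  if (!length(lcand)) return(list(p2p = 0, degenerate = TRUE, high = high))
  low <- min(vapply(lcand, win_mean, numeric(1)))
  list(p2p = high - low, degenerate = FALSE, high = high, low = low)
}

# brute-force latency oracle: argmax over every enumerated window
latency_oracle <- function(values, times, bound_start, bound_end, inner) {
  fs <- 1000 / (times[2] - times[1])
  L <- round(inner * fs / 1000)
  cand <- Filter(function(i) times[i] >= bound_start - 1e-9 &&
                   i + L - 1 <= length(values) &&
                   times[i] + inner <= bound_end + 1e-9, seq_along(values))
  means <- vapply(cand, function(i) mean(values[i:(i + L - 1)]), numeric(1))
  times[cand[which.max(means)]]
}

# random epoch set for round-trip property tests
random_es <- function(fs = 100) {
  n_cond <- sample(1:3, 1)
  conds <- paste0("C", seq_len(n_cond))
  n_ch <- sample(1:3, 1)
  channels <- paste0("ch", seq_len(n_ch))
  n_samp <- 10
  arrs <- lapply(conds, function(cc)
    noise_array(sample(1:4, 1), n_ch, n_samp, sd = 20))
  names(arrs) <- conds
  n_tr <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  make_es(arrs, channels, fs = fs, start = -20,
          chrono = sample.int(n_tr * 2, n_tr),
          valid = runif(n_tr) > 0.2,
          subject = paste0("R", sample.int(99, 1)))
}
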