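#' Paired t-test across subjects
#'
#' Thin wrapper around \code{stats::t.test(..., paired = TRUE)} returning the
#' pieces the group analyses need, with an explicit degenerate flag where the
#' paired differences have zero variance (t.test refuses essentially-constant
#' data): all-zero differences give t = 0, p = 1; a constant nonzero
#' difference gives p = 0 with infinite t.
#'
#' @param a,b Equal-length numeric vectors, paired by subject.
#' @return A list of class \code{"paired_t"}: \code{t}, \code{df}, \code{p},
#'   \code{ci95} (length-2), \code{mean_diff}, \code{n}, \code{degenerate}.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    md <- mean(d)
    return(structure(list(
      t = if (md == 0) 0 else sign(md) * Inf,
      df = n - 1,
      p = if (md == 0) 1 else 0,
      ci95 = c(md, md), mean_diff = md, n = n, degenerate = TRUE),
      class = "paired_t"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, ci95 = as.numeric(tt$conf.int),
                 mean_diff = unname(tt$estimate), n = n, degenerate = FALSE),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t-test: t(%g) = %.4g, p = %.4g, mean diff = %.4g, 95%% CI [%.4g, %.4g]%s\n",
              x$df, x$t, x$p, x$mean_diff, x$ci95[1], x$ci95[2],
              if (x$degenerate) " [degenerate: zero-variance differences]" else ""))
  invisible(x)
}

# per-subject p2p of (late - early) and (even - odd) ERPs at one channel
early_late_p2p_pair <- function(es, channel, params,
                                repeated = "Irrelevant2", baseline = "Irrelevant1") {
  halves <- split_half_chronological(es, repeated)
  dw_el <- difference_wave(average_erp(halves$late, repeated, channel),
                           average_erp(halves$early, repeated, channel))
  par <- split_parity(es, baseline)
  dw_eo <- difference_wave(average_erp(par$even, baseline, channel),
                           average_erp(par$odd, baseline, channel))
  c(early_late = peak_to_peak(dw_el, params)$p2p,
    even_odd = peak_to_peak(dw_eo, params)$p2p)
}

#' Early-late versus even-odd repetition control
#'
#' Tests whether repeated exposure changes the response to an irrelevant
#' stimulus. Per subject and channel: the peak-to-peak of the (Late - Early)
#' difference wave of the repeated condition is compared against the
#' peak-to-peak of the (Even - Odd) difference wave of the baseline
#' condition — a split in which no temporal effect can exist — via a paired
#' t-test across subjects.
#'
#' @param subjects List of \code{\link{epoch_set}}s, one per subject.
#' @param channels Channels analysed (default Fz, Cz, Pz).
#' @param params Named per-channel \code{\link{peak_params}} list (default:
#'   P3a presets at Fz/Cz, P3b at Pz).
#' @param repeated Condition split early/late (default \code{"Irrelevant2"}).
#' @param baseline Condition split even/odd (default \code{"Irrelevant1"}).
#' @return Named list, one \code{\link{paired_t}} per channel, each carrying
#'   the per-subject value matrix as attribute \code{"values"}.
#' @export
early_late_analysis <- function(subjects, channels = c("Fz", "Cz", "Pz"),
                                params = default_channel_params(channels),
                                repeated = "Irrelevant2",
                                baseline = "Irrelevant1") {
  stopifnot(length(subjects) >= 2)
  out <- list()
  for (ch in channels) {
    vals <- t(vapply(subjects, early_late_p2p_pair, numeric(2),
                     channel = ch, params = params[[ch]],
                     repeated = repeated, baseline = baseline))
    res <- paired_t(vals[, "early_late"], vals[, "even_odd"])
    attr(res, "values") <- vals
    out[[ch]] <- res
  }
  out
}

#' Fixed-effects latency-difference randomisation test
#'
#' Pools all trials of two conditions across subjects, measures the
#' windowed-maximum latency of each pooled grand average, and tests the
#' observed latency difference (first pool minus second, e.g. Fake - Probe)
#' against a null built by repeatedly drawing two disjoint m-sized surrogate
#' pools from the merged trials (m = the smaller pool size, reduced to
#' floor(total/2) with a warning if two disjoint m-sets cannot fit).
#'
#' @param fake,probe Trials x samples matrices of single-trial waveforms for
#'   one channel (build them with \code{\link{pool_matrix}}), or the output
#'   of \code{pool_matrix} directly.
#' @param times ms grid; taken from the \code{"times"} attribute of
#'   \code{fake} when omitted.
#' @param lp A \code{\link{latency_params}} object.
#' @param B Resample count (default 1000).
#' @param seed Optional RNG seed.
#' @return List of class \code{"latency_test"}: \code{observed_diff} (ms,
#'   fake minus probe), \code{null_diffs} (length B), \code{p}, \code{m}.
#' @export
latency_difference_test <- function(fake, probe, lp, times = attr(fake, "times"),
                                    B = 1000, seed = NULL) {
  stopifnot(inherits(lp, "latency_params"), B >= 2)
  if (is.null(times)) stop("supply times or a pool with a times attribute")
  if (!is.null(seed)) set.seed(seed)
  nf <- nrow(fake); np <- nrow(probe)
  if (nf < 1 || np < 1) stop("both pools must be nonempty")
  obs <- latency(waveform("pool", times, colMeans(fake)), lp) -
    latency(waveform("pool", times, colMeans(probe)), lp)

  X <- rbind(fake, probe)
  total <- nf + np
  m <- min(nf, np)
  if (2 * m > total) {
    m <- floor(total / 2)
    warning("pools overlap too much for two disjoint m-sets; reducing m to ", m)
  }
  # B draws of two disjoint m-sets: signed membership operator then one matmul
  A <- matrix(0, B, total)
  for (b in seq_len(B)) {
    idx <- sample.int(total, 2 * m)
    A[b, idx[seq_len(m)]] <- 1 / m
    A[b, idx[m + seq_len(m)]] <- -1 / m
  }
  # latency of each surrogate grand average separately, then their difference
  A1 <- pmax(A, 0); A2 <- -pmin(A, 0)
  l1 <- latency_matrix(A1 %*% X, times, lp)
  l2 <- latency_matrix(A2 %*% X, times, lp)
  null_diffs <- l1 - l2
  structure(list(observed_diff = obs, null_diffs = null_diffs,
                 p = mean(null_diffs > obs), m = m, B = B),
            class = "latency_test")
}

#' @export
print.latency_test <- function(x, ...) {
  cat(sprintf("Latency difference test: observed %+g ms, p = %s (B = %d, m = %d)\n",
              x$observed_diff, p_display(x$p, x$B), x$B, x$m))
  invisible(x)
}

#' Group contrast of per-subject peak-to-peak values
#'
#' Convenience wrapper: for each subject, peak-to-peak of the
#' (condition minus reference) difference wave at one channel for two
#' conditions, then a paired t-test across subjects — e.g. Probe vs
#' Irrelevant2, both referenced to Irrelevant1.
#'
#' @param subjects List of \code{\link{epoch_set}}s.
#' @param channel Channel analysed.
#' @param cond_a,cond_b The two contrasted conditions (defaults
#'   \code{"Probe"}, \code{"Irrelevant2"}).
#' @param reference Baseline condition subtracted from both (default
#'   \code{"Irrelevant1"}).
#' @param params \code{\link{peak_params}}; defaults to the channel's preset.
#' @return A \code{\link{paired_t}} with the per-subject value matrix as
#'   attribute \code{"values"}.
#' @export
group_p2p_contrast <- function(subjects, channel, cond_a = "Probe",
                               cond_b = "Irrelevant2",
                               reference = "Irrelevant1",
                               params = default_channel_params(channel)[[channel]]) {
  p2p_of <- function(es, cond) {
    dw <- difference_wave(average_erp(es, cond, channel),
                          average_erp(es, reference, channel))
    peak_to_peak(dw, params)$p2p
  }
  a <- vapply(subjects, p2p_of, numeric(1), cond = cond_a)
  b <- vapply(subjects, p2p_of, numeric(1), cond = cond_b)
  res <- paired_t(a, b)
  attr(res, "values") <- cbind(a = a, b = b)
  res
}
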