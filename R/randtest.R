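#' First-level per-electrode randomisation test
#'
#' Under the null hypothesis, Probe and Irrelevant trials are exchangeable
#' samples from one distribution. The test matches trial counts (m = the
#' smaller valid count), pools the 2m matched trials, and repeatedly
#' relabels them into two m-sized surrogate groups; the peak-to-peak of the
#' surrogate-ERP difference, per electrode, forms the null distribution.
#' Because the peak search optimises window placement on every resample, the
#' null embodies the maximal statistic and no multiple-comparison correction
#' over window placements is needed. One relabelling is shared by all
#' electrodes (a trial is a triple across Fz/Cz/Pz), preserving
#' cross-electrode correlation. The observed statistic is computed from the
#' ERPs over \emph{all} valid trials, not just the m-subsets.
#'
#' @param probe An \code{\link{epoch_set}} holding the (notional) Probe
#'   condition's trials; only one condition's trials should be present (see
#'   \code{\link{cit_detect}} for the full pipeline).
#' @param irrelevant An \code{epoch_set} with the baseline condition's trials,
#'   on the same grid and channels.
#' @param probe_condition,irrelevant_condition Condition labels to pull from
#'   each set; defaults to every valid trial in the set.
#' @param B Number of resamples (default 1000).
#' @param channels Electrodes analysed (default Fz, Cz, Pz).
#' @param params Named list mapping each channel to a
#'   \code{\link{peak_params}} object; defaults to the P3a preset at Fz/Cz
#'   and P3b at Pz.
#' @return A list of class \code{"first_level"}: \code{m}, \code{observed}
#'   (named per-channel peak-to-peak, microvolts), \code{null_matrix}
#'   (\code{B x length(channels)}), \code{p_per_channel} (strict-inequality
#'   Monte-Carlo p-values, granularity 1/B), \code{B}, \code{channels}.
#' @export
first_level <- function(probe, irrelevant,
                        probe_condition = NULL, irrelevant_condition = NULL,
                        B = 1000, channels = c("Fz", "Cz", "Pz"),
                        params = default_channel_params(channels)) {
  stopifnot(B >= 2, length(channels) >= 1)
  if (max(abs(probe$times - irrelevant$times)) > 1e-9)
    stop("epoch sets do not share a time grid")
  pi_ <- if (is.null(probe_condition)) which(probe$trials$valid) else
    valid_idx(probe, probe_condition)
  ii <- if (is.null(irrelevant_condition)) which(irrelevant$trials$valid) else
    valid_idx(irrelevant, irrelevant_condition)
  if (length(pi_) < 2 || length(ii) < 2)
    stop("need at least 2 valid trials in each condition (have ",
         length(pi_), " and ", length(ii), ")")
  m <- min(length(pi_), length(ii))

  # random m-subsets, without replacement (draw order: probe then irrelevant)
  sel_p <- sample(pi_, m)
  sel_i <- sample(ii, m)

  # shared relabellings across channels: B permutations of the 2m pool
  perm1 <- t(replicate(B, sample.int(2 * m, m)))  # B x m group-1 indices

  chp <- match(channels, probe$channels)
  chi <- match(channels, irrelevant$channels)
  if (anyNA(chp) || anyNA(chi)) stop("channel missing from epoch set")

  times <- probe$times
  observed <- numeric(length(channels))
  null_matrix <- matrix(NA_real_, B, length(channels),
                        dimnames = list(NULL, channels))
  # group-1 trial-sum operator: A[b, j] = 1 if pooled trial j in group 1
  A <- matrix(0, B, 2 * m)
  A[cbind(rep(seq_len(B), m), as.vector(perm1))] <- 1

  for (k in seq_along(channels)) {
    Xp <- probe$data[sel_p, chp[k], , drop = FALSE]
    dim(Xp) <- c(m, length(times))
    Xi <- irrelevant$data[sel_i, chi[k], , drop = FALSE]
    dim(Xi) <- c(m, length(times))
    X <- rbind(Xp, Xi)                       # 2m x samples pool
    tot <- colSums(X)
    D <- (2 * (A %*% X) - rep(tot, each = B)) / m  # surrogate difference waves
    null_matrix[, k] <- peak_to_peak_matrix(D, times, params[[channels[k]]])

    # observed: full valid-trial ERPs, not the m-subsets
    Op <- probe$data[pi_, chp[k], , drop = FALSE]
    dim(Op) <- c(length(pi_), length(times))
    Oi <- irrelevant$data[ii, chi[k], , drop = FALSE]
    dim(Oi) <- c(length(ii), length(times))
    dw <- waveform(channels[k], times, colMeans(Op) - colMeans(Oi))
    observed[k] <- peak_to_peak(dw, params[[channels[k]]])$p2p
  }
  names(observed) <- channels
  p <- colMeans(null_matrix > rep(observed, each = B))
  structure(list(m = m, observed = observed, null_matrix = null_matrix,
                 p_per_channel = p, B = B, channels = channels),
            class = "first_level")
}

#' Per-resample p-values within each null column
#'
#' For each resample statistic d, the proportion of the B statistics in its
#' own column strictly above d. A value is never above itself, so attainable
#' p-values are 0, 1/B, ..., (B-1)/B.
#'
#' @param null_matrix \code{B x n_channels} matrix of resample statistics.
#' @return Matrix of the same shape with p-values.
#' @export
per_resample_pvalues <- function(null_matrix) {
  B <- nrow(null_matrix)
  stopifnot(B >= 2)
  apply(null_matrix, 2, function(x) (B - rank(x, ties.method = "max")) / B)
}

#' Fisher combined score of per-dimension p-values
#'
#' The combining statistic -2 * sum(log p): monotone decreasing in the
#' product of the p-values. Exact zeros — the floor of a B-resample test —
#' are replaced by the smallest legitimate p-value 1/B (0.001 at B = 1000)
#' so the score stays finite. In this pipeline the score is referenced
#' against its own resampled null, never against a chi-squared table, so any
#' strictly decreasing function of the product would give the same combined
#' p-value.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param B Resample count defining the zero replacement 1/B.
#' @return The Fisher score (scalar).
#' @export
fisher_score <- function(p, B = 1000) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p[p == 0] <- 1 / B
  -2 * sum(log(p))
}

# Row-wise Fisher scores of a p-value matrix
fisher_scores_rows <- function(P, B) {
  P[P == 0] <- 1 / B
  -2 * rowSums(log(P))
}

#' Second-level Fisher combination across electrodes
#'
#' Converts each row of the first-level null matrix into per-dimension
#' p-values (against its own column), Fisher-scores each row and the observed
#' p-vector, and locates the observed score in the null score distribution.
#'
#' @param fl A \code{\link{first_level}} result.
#' @return A list of class \code{"combined_result"}: \code{fisher_observed},
#'   \code{fisher_null} (length B), \code{fisher_p}.
#' @export
combined_p <- function(fl) {
  stopifnot(inherits(fl, "first_level"))
  P <- per_resample_pvalues(fl$null_matrix)
  fisher_null <- fisher_scores_rows(P, fl$B)
  fisher_observed <- fisher_score(fl$p_per_channel, fl$B)
  structure(list(fisher_observed = fisher_observed,
                 fisher_null = fisher_null,
                 fisher_p = mean(fisher_null > fisher_observed)),
            class = "combined_result")
}

#' Per-subject concealed-information detection
#'
#' The full single-subject pipeline: baseline correction, amplitude-based
#' artifact rejection, per-electrode peak-to-peak randomisation tests of the
#' probe condition against the irrelevant baseline, and Fisher combination
#' across electrodes. The decision is \code{fisher_p < alpha}.
#'
#' @param es An \code{\link{epoch_set}} containing at least the probe and
#'   irrelevant conditions.
#' @param probe,irrelevant Condition labels (defaults \code{"Probe"},
#'   \code{"Irrelevant1"}).
#' @param B Resample count (default 1000); p-value granularity is 1/B.
#' @param alpha Decision level (default 0.05).
#' @param channels Electrodes analysed; default Fz, Cz, Pz with the P3a
#'   presets at Fz/Cz and the P3b preset at Pz.
#' @param params Named per-channel \code{\link{peak_params}} list.
#' @param baseline Baseline window in ms, or \code{NULL} to skip correction.
#' @param reject_threshold Artifact rejection threshold in microvolts, or
#'   \code{NULL} to skip rejection.
#' @param seed Optional integer; when given, seeds one RNG stream for the
#'   whole call (trial matching first, then resample shuffles) so reports are
#'   bit-reproducible.
#' @return An object of class \code{"cit_detection"} with fields
#'   \code{subject_id}, \code{m}, \code{observed}, \code{p_per_channel},
#'   \code{fisher_observed}, \code{fisher_p}, \code{alpha}, \code{decision},
#'   \code{B}, \code{seed}, \code{n_valid}, plus the underlying
#'   \code{first_level} and \code{combined_result} for inspection/plotting.
#' @seealso \code{\link{write_report}}, \code{\link{intrinsic_fp_rate}}
#' @export
cit_detect <- function(es, probe = "Probe", irrelevant = "Irrelevant1",
                       B = 1000, alpha = 0.05,
                       channels = c("Fz", "Cz", "Pz"),
                       params = default_channel_params(channels),
                       baseline = c(-100, 0), reject_threshold = 50,
                       seed = NULL) {
  stopifnot(alpha > 0, alpha <= 1)
  if (!all(c(probe, irrelevant) %in% es$trials$condition))
    stop("conditions ", probe, " and ", irrelevant, " must both be present")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(baseline)) es <- baseline_correct(es, baseline)
  if (!is.null(reject_threshold))
    es <- reject_amplitude(es, reject_threshold, channels = channels)

  fl <- first_level(es, es, probe_condition = probe,
                    irrelevant_condition = irrelevant,
                    B = B, channels = channels, params = params)
  cmb <- combined_p(fl)
  structure(list(
    subject_id = es$subject_id,
    channels = channels,
    m = fl$m,
    observed = fl$observed,
    p_per_channel = fl$p_per_channel,
    fisher_observed = cmb$fisher_observed,
    fisher_p = cmb$fisher_p,
    alpha = alpha,
    decision = cmb$fisher_p < alpha,
    B = B,
    seed = seed,
    n_valid = valid_counts(es),
    first_level = fl,
    combined = cmb
  ), class = "cit_detection")
}

#' @export
print.cit_detection <- function(x, ...) {
  cat("Single-subject concealed-information detection\n")
  cat(sprintf("  subject: %s   m = %d matched trials, B = %d resamples\n",
              x$subject_id, x$m, x$B))
  for (ch in x$channels)
    cat(sprintf("  %-3s observed p2p = %8.3f uV   p = %s\n", ch,
                x$observed[[ch]], p_display(x$p_per_channel[[ch]], x$B)))
  cat(sprintf("  Fisher combined p = %s  =>  %s at alpha = %g\n",
              p_display(x$fisher_p, x$B),
              if (x$decision) "DETECTED" else "not detected", x$alpha))
  invisible(x)
}

#' @export
summary.cit_detection <- function(object, ...) {
  out <- data.frame(dimension = c(object$channels, "Fisher"),
                    observed = c(unname(object$observed), object$fisher_observed),
                    p = c(unname(object$p_per_channel), object$fisher_p))
  attr(out, "decision") <- object$decision
  out
}

#' @export
plot.cit_detection <- function(x, ...) {
  graphics::hist(x$combined$fisher_null, breaks = 30,
       main = sprintf("Fisher null, subject %s (p = %s)", x$subject_id,
                      p_display(x$fisher_p, x$B)),
       xlab = "Fisher score", ...)
  graphics::abline(v = x$fisher_observed, lwd = 2)
  invisible(x)
}
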