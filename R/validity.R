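#' Fabricate a null dataset from a no-signal epoch pool
#'
#' Draws \code{4 * n_per_condition} artifact-free epochs from the pool
#' without replacement and relabels them, fully at random, into four
#' fabricated conditions of equal size. Because the epochs are real (or
#' realistically simulated) no-signal EEG, the fabricated dataset preserves
#' background temporal correlations while the null hypothesis holds by
#' construction.
#'
#' @param noise_pool An \code{\link{epoch_set}} of no-signal epochs (e.g.
#'   distractor-locked segments); every valid trial is eligible regardless of
#'   its original label.
#' @param n_per_condition Epochs per fabricated condition (default 50).
#' @param conditions The four fabricated labels.
#' @param seed Optional RNG seed.
#' @return An \code{\link{epoch_set}} with \code{4 * n_per_condition} trials,
#'   chronological indices renumbered 1..4n in draw order.
#' @export
fabricate_null_dataset <- function(noise_pool, n_per_condition = 50,
                                   conditions = c("Probe", "Fake",
                                                  "Irrelevant1", "Irrelevant2"),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- which(noise_pool$trials$valid)
  need <- length(conditions) * n_per_condition
  if (length(pool) < need)
    stop("pool has ", length(pool), " artifact-free epochs; need ", need)
  draw <- sample(pool, need)
  out <- subset_trials(noise_pool, draw)
  out$trials$chrono_index <- seq_len(need)
  out$trials$condition <- rep(conditions, each = n_per_condition)
  out$conditions <- conditions
  out
}

#' Intrinsic false-positive rate by null simulation
#'
#' Repeatedly fabricates null datasets from a no-signal pool and runs the
#' full detection pipeline on each; the fraction of runs with p below alpha
#' estimates the intrinsic type-I error rate of the statistic, which should
#' sit at the alpha level, with mean null p near 0.5.
#'
#' @param noise_pool An \code{\link{epoch_set}} of no-signal epochs.
#' @param R Number of fabricated datasets (runs).
#' @param B Resamples per run.
#' @param alpha Significance level (default 0.05).
#' @param n_per_condition Epochs per fabricated condition.
#' @param channels,params Electrodes and per-channel
#'   \code{\link{peak_params}}, as in \code{\link{cit_detect}}.
#' @param seed Optional seed for the whole simulation.
#' @return List of class \code{"validity_run"}: \code{p} (R x dims matrix,
#'   columns the channels plus \code{"Fisher"}), \code{fp_rate},
#'   \code{mean_p} (named per dimension), \code{R}, \code{B}, \code{alpha}.
#' @export
intrinsic_fp_rate <- function(noise_pool, R, B = 1000, alpha = 0.05,
                              n_per_condition = 50,
                              channels = c("Fz", "Cz", "Pz"),
                              params = default_channel_params(channels),
                              seed = NULL) {
  stopifnot(R >= 1)
  if (!is.null(seed)) set.seed(seed)
  dims <- c(channels, "Fisher")
  p <- matrix(NA_real_, R, length(dims), dimnames = list(NULL, dims))
  for (r in seq_len(R)) {
    fab <- fabricate_null_dataset(noise_pool, n_per_condition)
    det <- cit_detect(fab, B = B, alpha = alpha, channels = channels,
                      params = params, baseline = NULL,
                      reject_threshold = NULL)
    p[r, ] <- c(det$p_per_channel, det$fisher_p)
  }
  structure(list(p = p, fp_rate = colMeans(p < alpha), mean_p = colMeans(p),
                 R = R, B = B, alpha = alpha), class = "validity_run")
}

#' @export
print.validity_run <- function(x, ...) {
  cat(sprintf("Intrinsic validity run: R = %d fabricated null datasets, B = %d, alpha = %g\n",
              x$R, x$B, x$alpha))
  out <- rbind(`FP rate` = x$fp_rate, `Avg p` = x$mean_p)
  print(round(out, 3))
  invisible(x)
}

#' Pairwise null screen over three no-signal conditions
#'
#' For three conditions in which no signal should exist (e.g. three
#' irrelevant names recorded from a control subject), runs the detection
#' pipeline on every ordered pair — six in all — with the first member
#' playing the notional Probe and the second the Irrelevant baseline. Under
#' the null, significant results should occur at roughly the alpha rate.
#'
#' @param es An \code{\link{epoch_set}} containing the three conditions.
#' @param conditions Character vector of exactly three distinct condition
#'   labels.
#' @param ... Passed to \code{\link{cit_detect}} (B, alpha, channels, ...).
#' @return Named list of six \code{cit_detection} objects, names
#'   \code{"X_vs_Y"}.
#' @export
pairwise_null_screen <- function(es, conditions = c("Irrelevant1",
                                                    "Irrelevant2",
                                                    "Irrelevant3"), ...) {
  if (length(conditions) != 3 || anyDuplicated(conditions))
    stop("need exactly three distinct no-signal conditions")
  miss <- setdiff(conditions, es$trials$condition)
  if (length(miss)) stop("condition(s) missing: ", paste(miss, collapse = ", "))
  pairs <- expand.grid(y = conditions, x = conditions,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$x != pairs$y, c("x", "y")]
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    x <- pairs$x[i]; y <- pairs$y[i]
    out[[paste0(x, "_vs_", y)]] <- cit_detect(es, probe = x, irrelevant = y, ...)
  }
  out
}
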