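#' Specify an ERP component template
#'
#' Components are sums of one or two Gaussians in time: a positive deflection
#' and, for biphasic shapes, a following negative deflection — enough to
#' express both the fronto-central P3a full oscillation cycle (sharp positive
#' then negative) and the broad, smeared parietal P3b. Amplitude topography
#' is a per-channel gain.
#'
#' @param channel_weights Named numeric vector, gain per channel.
#' @param shape \code{"biphasic"} or \code{"monophasic"}.
#' @param pos_peak,pos_width,pos_amp Positive deflection: peak time (ms),
#'   Gaussian sigma (ms), amplitude (microvolts).
#' @param neg_peak,neg_width,neg_amp Negative deflection (biphasic only);
#'   \code{neg_amp} must be <= 0 and \code{neg_peak > pos_peak}.
#' @param latency_jitter_sd Per-trial latency jitter SD in ms (one draw
#'   shifts both deflections).
#' @return A list of class \code{"component_spec"}.
#' @export
component_spec <- function(channel_weights, shape = c("biphasic", "monophasic"),
                           pos_peak, pos_width, pos_amp,
                           neg_peak = NULL, neg_width = NULL, neg_amp = 0,
                           latency_jitter_sd = 0) {
  shape <- match.arg(shape)
  stopifnot(pos_width > 0)
  if (shape == "biphasic") {
    stopifnot(!is.null(neg_peak), !is.null(neg_width), neg_width > 0,
              neg_amp <= 0, pos_peak < neg_peak)
  }
  structure(list(channel_weights = channel_weights, shape = shape,
                 pos_peak = pos_peak, pos_width = pos_width, pos_amp = pos_amp,
                 neg_peak = neg_peak, neg_width = neg_width, neg_amp = neg_amp,
                 latency_jitter_sd = latency_jitter_sd),
            class = "component_spec")
}

#' Evaluate a component template on a time grid
#'
#' @param spec A \code{\link{component_spec}}.
#' @param times ms grid.
#' @param jitter Latency shift in ms applied to both deflections.
#' @param channel Optional channel name; when given, values are scaled by
#'   that channel's weight (unknown channels get gain 0).
#' @return Numeric vector of amplitudes (microvolts).
#' @export
component_waveform <- function(spec, times, jitter = 0, channel = NULL) {
  v <- spec$pos_amp * exp(-(times - spec$pos_peak - jitter)^2 / (2 * spec$pos_width^2))
  if (spec$shape == "biphasic")
    v <- v + spec$neg_amp * exp(-(times - spec$neg_peak - jitter)^2 / (2 * spec$neg_width^2))
  if (!is.null(channel)) {
    g <- spec$channel_weights[channel]
    v <- v * if (is.na(g)) 0 else unname(g)
  }
  v
}

#' Synthetic-cohort configuration
#'
#' Defaults emulate the RSVP own-name paradigm at desk scale: 50 trials per
#' condition, epochs [-100, 1000) ms at 250 Hz on Fz/Cz/Pz, 1/f background
#' noise of 10 microvolts SD plus a 10 Hz alpha sinusoid with random phase
#' per trial, moderate cross-channel noise correlation, and a pool of
#' distractor-locked no-component epochs for null fabrication.
#'
#' @param n_subjects Number of subjects.
#' @param trials_per_condition Trials per condition (default 50).
#' @param sampling_rate Hz (default 250).
#' @param epoch_start,epoch_end Epoch extent in ms.
#' @param channels Channel names.
#' @param noise_sd SD of the stochastic background per channel (microvolts).
#' @param noise_model \code{"one_over_f"} (default) or \code{"white"}.
#' @param alpha_amp Amplitude of the 10 Hz alpha sinusoid (microvolts).
#' @param channel_noise_correlation Pairwise background correlation in [0, 1].
#' @param components Named list: condition label -> list of
#'   \code{\link{component_spec}}s added to that condition's trials.
#' @param distractor_pool_size Extra no-component epochs labelled
#'   \code{"distractor"} (default 240).
#' @param amplitude_hyper_sd,latency_hyper_sd Between-subject SDs: a
#'   multiplicative amplitude factor (1 + N(0, sd), floored at 0.1) and an
#'   additive latency shift (ms) drawn once per subject.
#' @param seed Optional base seed; subject k uses \code{seed + k - 1}.
#' @return A list of class \code{"synth_config"}.
#' @export
synth_config <- function(n_subjects = 1, trials_per_condition = 50,
                         sampling_rate = 250, epoch_start = -100,
                         epoch_end = 1000, channels = c("Fz", "Cz", "Pz"),
                         noise_sd = 10, noise_model = c("one_over_f", "white"),
                         alpha_amp = 3, channel_noise_correlation = 0.3,
                         components = list(), distractor_pool_size = 240,
                         amplitude_hyper_sd = 0, latency_hyper_sd = 0,
                         seed = NULL) {
  stopifnot(trials_per_condition >= 2, noise_sd >= 0,
            channel_noise_correlation >= 0, channel_noise_correlation <= 1)
  structure(list(n_subjects = n_subjects,
                 trials_per_condition = trials_per_condition,
                 sampling_rate = sampling_rate, epoch_start = epoch_start,
                 epoch_end = epoch_end, channels = channels,
                 noise_sd = noise_sd, noise_model = match.arg(noise_model),
                 alpha_amp = alpha_amp,
                 channel_noise_correlation = channel_noise_correlation,
                 components = components,
                 distractor_pool_size = distractor_pool_size,
                 amplitude_hyper_sd = amplitude_hyper_sd,
                 latency_hyper_sd = latency_hyper_sd, seed = seed),
            class = "synth_config")
}

#' Preset cohort profiles
#'
#' \describe{
#'   \item{\code{"null"}}{background noise only, no components anywhere — the
#'     calibration profile.}
#'   \item{\code{"guilty"}}{the subject's own name is present as the Probe:
#'     Probe trials carry a biphasic fronto-central P3a (8 uV positive at
#'     240 ms, -6 uV negative at 400 ms, Fz/Cz-weighted) plus a parietal
#'     monophasic P3b (10 uV at 480 ms, Pz-weighted); Fake trials carry a
#'     slightly later P3a (280 ms) and a larger, later P3b (12 uV at 560 ms
#'     — the explicit task target), i.e. the Fake P3b trails the Probe by
#'     80 ms.}
#'   \item{\code{"innocent"}}{only the Fake components; the notional Probe is
#'     just another irrelevant name.}
#' }
#' Amplitudes are chosen so that observed peak-to-peak values land in the
#' 5-25 uV range typical of single-subject own-name experiments; they are
#' generator defaults, not ground truth.
#'
#' @param profile One of \code{"null"}, \code{"guilty"}, \code{"innocent"}.
#' @param ... Overrides passed to \code{\link{synth_config}}.
#' @return A \code{\link{synth_config}}.
#' @export
synth_profile <- function(profile = c("null", "guilty", "innocent"), ...) {
  profile <- match.arg(profile)
  p3a_w <- c(Fz = 1, Cz = 0.8, Pz = 0.15)
  p3b_w <- c(Fz = 0.1, Cz = 0.4, Pz = 1)
  probe_comps <- list(
    component_spec(p3a_w, "biphasic", pos_peak = 240, pos_width = 40,
                   pos_amp = 8, neg_peak = 400, neg_width = 60, neg_amp = -6,
                   latency_jitter_sd = 20),
    component_spec(p3b_w, "monophasic", pos_peak = 480, pos_width = 90,
                   pos_amp = 10, latency_jitter_sd = 30))
  fake_comps <- list(
    component_spec(p3a_w, "biphasic", pos_peak = 280, pos_width = 40,
                   pos_amp = 6, neg_peak = 440, neg_width = 60, neg_amp = -5,
                   latency_jitter_sd = 20),
    component_spec(p3b_w, "monophasic", pos_peak = 560, pos_width = 90,
                   pos_amp = 12, latency_jitter_sd = 30))
  comps <- switch(profile,
                  "null" = list(),
                  "guilty" = list(Probe = probe_comps, Fake = fake_comps),
                  "innocent" = list(Fake = fake_comps))
  synth_config(components = comps, ...)
}

# unit-SD 1/f (power ~ 1/f) noise via spectral synthesis
one_over_f_noise <- function(n, sampling_rate) {
  K <- floor((n - 1) / 2)
  f <- (1:K) * sampling_rate / n
  A <- 1 / sqrt(f)
  co <- complex(real = stats::rnorm(K) * A, imaginary = stats::rnorm(K) * A)
  spec <- complex(length.out = n)
  spec[2:(K + 1)] <- co
  spec[n + 1 - (1:K)] <- Conj(co)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / (sqrt(4 * sum(A^2)) / n)  # stationary SD of the synthesis is known exactly
}

# n_channels x n_samples correlated background for one trial, unit SD
background_noise <- function(n_ch, n, model, rho, sampling_rate) {
  gen <- function() if (model == "white") stats::rnorm(n) else
    one_over_f_noise(n, sampling_rate)
  shared <- gen()
  t(vapply(seq_len(n_ch),
           function(i) sqrt(rho) * shared + sqrt(1 - rho) * gen(),
           numeric(n)))
}

#' Simulate one subject's epoch set
#'
#' Each trial is correlated background noise (per \code{noise_model}), a
#' shared-phase 10 Hz alpha sinusoid, and the sum of the condition's
#' component templates with a per-trial latency jitter draw per component.
#' Chronological indices interleave all conditions (and the distractor pool)
#' in random order, emulating a randomised trial sequence.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @param subject_index 1-based subject number; offsets the seed and names
#'   the subject.
#' @return An \code{\link{epoch_set}} (already baseline-free by construction;
#'   running \code{\link{baseline_correct}} is still harmless).
#' @export
simulate_subject <- function(cfg, subject_index = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed + subject_index - 1)
  times <- epoch_time_grid(cfg$epoch_start, cfg$epoch_end, cfg$sampling_rate)
  n_samp <- length(times)
  n_ch <- length(cfg$channels)

  # between-subject perturbations (no-ops at hyper-SD 0)
  amp_f <- max(0.1, 1 + stats::rnorm(1, 0, cfg$amplitude_hyper_sd))
  lat_s <- stats::rnorm(1, 0, cfg$latency_hyper_sd)
  if (cfg$amplitude_hyper_sd == 0) amp_f <- 1
  if (cfg$latency_hyper_sd == 0) lat_s <- 0

  cond_labels <- unique(c(names(cfg$components),
                          c("Probe", "Fake", "Irrelevant1", "Irrelevant2")))
  n_main <- length(cond_labels) * cfg$trials_per_condition
  total <- n_main + cfg$distractor_pool_size
  condition <- c(rep(cond_labels, each = cfg$trials_per_condition),
                 rep("distractor", cfg$distractor_pool_size))

  data <- array(0, dim = c(total, n_ch, n_samp))
  for (i in seq_len(total)) {
    tr <- if (cfg$noise_sd > 0)
      cfg$noise_sd * background_noise(n_ch, n_samp, cfg$noise_model,
                                      cfg$channel_noise_correlation,
                                      cfg$sampling_rate)
    else matrix(0, n_ch, n_samp)
    if (cfg$alpha_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      tr <- tr + rep(cfg$alpha_amp * sin(2 * pi * 10 * times / 1000 + phase),
                     each = n_ch)
    }
    comps <- cfg$components[[condition[i]]]
    if (!is.null(comps)) for (cs in comps) {
      jit <- lat_s + if (cs$latency_jitter_sd > 0)
        stats::rnorm(1, 0, cs$latency_jitter_sd) else 0
      base <- component_waveform(cs, times, jitter = jit)
      w <- cs$channel_weights[cfg$channels]
      w[is.na(w)] <- 0
      tr <- tr + amp_f * outer(unname(w), base)
    }
    data[i, , ] <- tr
  }

  trials <- data.frame(chrono_index = sample.int(total),
                       condition = condition,
                       valid = TRUE)
  epoch_set(subject_id = sprintf("S%02d", subject_index),
            sampling_rate = cfg$sampling_rate, channels = cfg$channels,
            trials = trials, data = data,
            epoch_start = cfg$epoch_start, epoch_end = cfg$epoch_end,
            conditions = c(cond_labels, "distractor"))
}

#' Simulate a cohort of independent subjects
#'
#' @param cfg A \code{\link{synth_config}}; \code{n_subjects} subjects are
#'   generated, each with its own seeded stream and (when the hyper-SDs are
#'   positive) its own amplitude/latency perturbation.
#' @return List of \code{\link{epoch_set}}s.
#' @export
simulate_cohort <- function(cfg) {
  lapply(seq_len(cfg$n_subjects), function(k) simulate_subject(cfg, k))
}
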