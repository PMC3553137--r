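---
title: "Peak-to-peak randomisation and Fisher combination for single-subject ERP detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-to-peak randomisation and Fisher combination for single-subject ERP detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(citerp)
```

## The inference problem

In an RSVP concealed-information paradigm, each trial is a rapid stream of
names containing one critical item: the subject's real name (Probe), an
assumed name they are instructed to respond to (Fake), or an unknown
control name (Irrelevant). Salient items break through into awareness and
elicit P3 activity; irrelevant items do not. The statistical task is
unusual for ERP work in that the unit of inference is a *single subject*:
given ~50 trials per condition, decide whether the Probe evoked a response
distinguishable from the Irrelevant baseline.

Two features make naive tests unusable. First, the measures of interest —
where exactly within a broad window the positive and negative peaks sit —
are optimised per subject, which would invite severe multiple-comparison
problems under parametric testing. Second, peak-to-peak measures are
positively biased on pure noise (a maximum minus a later minimum), so
comparing them against zero is meaningless. The package's design answers
both with a randomisation test whose null distribution re-optimises the
measure on every resample (the maximal-statistic logic), and with
baselines that are themselves subject to the same bias (Irrelevant2 vs
Irrelevant1, Even vs Odd splits).

## The measurement model

Epochs span [-100, 1000) ms around critical-item onset on a uniform grid
(sample count = `round(span * rate / 1000)`, samples at left edges — the
half-open convention makes counts unambiguous at any rate). Amplitudes are
microvolts; each trial is baseline-corrected by subtracting its mean over
[-100, 0) ms, and trials with any sample strictly beyond ±50 µV on an
analysed channel are flagged invalid and excluded from every average and
resample. The threshold is strict (a sample at exactly ±50 µV survives)
and applies only to analysed channels, since ocular-artifact handling is
assumed to have happened upstream.

A "peak" is never a single sample: it is the mean over a 100 ms *inner
window*, slid one sample at a time across a *bounding window*, and only
placements lying wholly inside the bound count. The peak-to-peak statistic
finds the highest inner-window mean, then searches from the first
non-overlapping sample position after it for the lowest mean, and reports
highest minus lowest. Per-electrode parameters:

| preset | bounding (ms) | inner (ms) | high-peak cap |
|---|---|---|---|
| P3a (Fz, Cz) | 150–1000 | 100 | window must end by 300 ms |
| P3b (Pz) | 300–1000 | 100 | none |
| P3a latency | 150–400 | 50 | — |
| P3b latency | 300–1000 | 100 | — |

The P3a cap prevents the (typically larger, later) P3b from being claimed
as the P3a's positive peak. We read "the search ends at 300 ms" as
constraining the *end* of the highest-peak window: that reading is the one
that actually guarantees no overlap of the P3a high peak into the P3b
region, which is the cap's stated purpose. The bound is configurable for
anyone preferring the start-constrained reading. Two consequences of the
cap are worth noting: the capped statistic can legitimately be negative
(the best pre-300 ms window may have a negative mean while the later
minimum is higher), whereas the uncapped statistic is non-negative on
every non-degenerate input; and if no full window fits after the highest
peak, the statistic is defined as 0 with a degenerate flag rather than an
error — the conservative "no biphasic component" verdict.

Ties in any argmax/argmin go to the earliest start, making results
deterministic and independent of trial storage order.

## The randomisation test

Let m be the smaller number of valid trials between Probe and Irrelevant1.
m trials are drawn from each condition (without replacement), pooled, and
B = 1000 times relabelled into two m-sized groups; each relabelling yields
surrogate ERPs, a surrogate difference wave, and a surrogate peak-to-peak
per electrode. One relabelling serves all electrodes simultaneously — a
trial is a triple of Fz/Cz/Pz segments — so the null preserves the
cross-electrode correlation structure. The observed statistic, by
contrast, uses *all* valid trials of each condition (the subject's true
ERPs), not the m-subsets; the m-matching exists to make the two surrogate
groups exchangeable, not to throw away data from the observed measure.

p-values count strict exceedances, `#(null > observed)/B`, so ties count
toward significance and the attainable values are 0, 1/B, ..., 1. A
reported 0 means "below the resolution of the test" and is displayed as
`<1/B`.

For the second level, each resample i is assigned a per-electrode p-value
— the fraction of the B statistics in that electrode's null column
strictly above resample i's value (the resample's own value is excluded by
strictness, so the maximum attainable is (B-1)/B; including it would shift
every p by at most 1/B and change nothing downstream). Row i's p-triple is
scored with Fisher's statistic `-2 * sum(log p)`, zeros replaced by 1/B
(0.001 at B = 1000). The observed p-triple is scored identically, and the
combined p is the observed score's strict exceedance count among the B
null scores. Because the score is referenced against its own resampled
null rather than a chi-squared table, any strictly decreasing function of
the product of p-values would give the identical combined p; `-2 Σ ln p`
is used as the conventional form. The chi-squared reference appears in
this package only inside a property test of Fisher-vs-averaging behaviour,
never in the pipeline.

Numerical note: an exact tie between a surrogate statistic and the
observed one (which occurs with probability 1/C(2m, m) per resample — the
identity relabelling) is resolved at floating-point resolution, because
the surrogate path computes group means by matrix multiplication. The
oracle-equivalence tests therefore compare against the exhaustive
permutation null as a ties-in/ties-out band; at realistic trial counts the
event is negligible.

## Calibration by construction

The intrinsic-validity simulation asks whether the whole pipeline's type-I
error equals its nominal alpha. Epochs that cannot contain signal
(distractor-locked segments) are pooled; 200 of them (4 × 50) are drawn
without replacement and relabelled fully at random into fabricated Probe,
Fake, Irrelevant1 and Irrelevant2 conditions; the standard analysis runs
unchanged. Over many fabricated datasets the combined p should be uniform:
false-positive rate ≈ alpha, mean p ≈ 0.5. Using real (or realistically
autocorrelated synthetic) background epochs matters — the argument needs
exchangeable no-signal epochs with genuine temporal structure, not white
noise. The empirical-null screen extends this to whole recordings: three
irrelevant conditions yield six ordered (notional-Probe, baseline) pairs,
each analysed by the standard pipeline.

Validation scales used by this package's own test suite: 15 synthetic
subjects × 200 fabricated datasets × B = 200 for the calibration check
(each per-dimension FP rate expected within ±0.02 of 0.05, pooled binomial
s.e. ≈ 0.004), R = 500 × B = 100 for the uniformity chi-squared, 100
subjects for amplitude power, 20 runs for latency power. These sizes give
comfortable statistical resolution at desk scale; the same machinery runs
unchanged at B = 1000 and R = 1000.

## Control analyses

*Early–late vs even–odd.* If repeated exposure taught subjects to perceive
an irrelevant name, late Irrelevant2 trials would show more P3 than early
ones. Valid Irrelevant2 trials are split chronologically (first ⌈n/2⌉
early — the ceiling rule is our choice, exposed in the API); the
peak-to-peak of the Late−Early difference wave is compared, across
subjects, against the peak-to-peak of the Even−Odd Irrelevant1 difference
wave, a split in which no temporal effect can exist but which carries the
same peak-to-peak noise bias. Parity is assigned on the within-condition
chronological *rank*, not the raw trial index, so interleaved conditions
and rejected trials cannot skew the halves. The comparison is an ordinary
paired t-test (`stats::t.test`), with zero-variance differences flagged
degenerate rather than erroring.

*Latency difference.* Probe and Fake pools are aggregated across subjects
(fixed effects: every trial weighs equally, so subjects with more valid
trials weigh more). The latency statistic is the start of the
maximal-mean inner window of the pooled grand average; the observed
Fake−Probe latency difference is referenced against B surrogate
differences obtained by drawing two disjoint m-sized sets from the merged
pool (m = smaller pool; if overlap-heavy pools make 2m exceed the total, m
drops to ⌊total/2⌋ with a warning). Surrogate sets are drawn uniformly
from the merged pool without stratifying by subject — the literal reading
of a fixed-effects null.

## The synthetic generator

`synth_profile()` emulates the paradigm's trial structure, not its
biophysics. Components are one- or two-Gaussian time templates with
per-channel gains: the guilty profile injects a biphasic fronto-central
P3a (8 µV positive at 240 ms, −6 µV at 400 ms) and a monophasic parietal
P3b (10 µV at 480 ms) into Probe trials, and a later, larger pair (P3a at
280 ms; P3b 12 µV at 560 ms) into Fake trials — amplitudes chosen to put
observed peak-to-peak values in the 5–25 µV range typical of own-name
data, and an 80 ms Fake−Probe P3b lag. Per-trial latency jitter (SD
20–30 ms) and optional between-subject amplitude/latency hyper-variation
provide random-effects structure. The background is 1/f-power noise
(spectral synthesis, analytically normalised to the configured SD, default
10 µV) plus a 10 Hz alpha sinusoid with per-trial random phase shared
across channels, with cross-channel correlation via a shared noise
component. The default rate is 250 Hz — digitisation rate is a free
configuration choice in this design, and 250 Hz resolves 100 ms windows
into 25 samples cheaply.

What the generator does *not* emulate: scalp topography beyond three
channels, non-stationary artifacts (blinks, drifts), subject-specific
component morphology beyond Gaussian shapes, overlap from adjacent stream
items, or any behavioural coupling. Passing calibration and power tests on
this generator therefore demonstrates the statistics are correct and
well-calibrated under realistic temporal autocorrelation; it does not
certify field performance on real recordings, where artifact handling and
electrode quality dominate.

Single-trial P3 variability in real data is essentially unknown; the
jitter defaults are assumptions, and raising `latency_jitter_sd` is the
first knob to turn when stress-testing the amplitude statistics against
smeared components.

## Other design choices and limitations

- Fabricated null conditions get equal sizes (configurable); real
  per-subject pool sizes would make them vary.
- The distractor pool accepts any artifact-free no-signal epochs; the
  construction only requires exchangeability, not a particular stream
  position bookkeeping.
- All randomness in a `cit_detect()` call flows from one seed: trial
  matching first, then relabellings — reports are byte-reproducible.
- Epoch interchange is a long-format TSV with a JSON sidecar, amplitudes
  printed at 17 significant digits so round trips are bit-exact; there are
  no importers for vendor formats (BrainVision/EDF/EEGLAB) yet.
- With-replacement bootstrap variants used elsewhere in the CIT literature
  are deliberately out of scope, as is hierarchical multi-subject
  inference: the group analyses here are fixed-effects or simple paired
  contrasts.
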