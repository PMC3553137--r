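# citerp

Single-subject detection of concealed, intrinsically salient information —
prototypically the subject's own name — from EEG recorded during rapid
serial visual presentation (RSVP), for researchers in ERP-based
concealed-information / deception detection and anyone who needs calibrated
per-individual inference on event-related potentials.

## The method

Words are streamed at one screen location (~7.5/s), too fast for explicit
report of every item, yet a salient item (the Probe: the subject's real
name) breaks through into awareness and elicits P3 components even while
the subject denies recognising it. Detection is per individual:

1. **Measure.** For electrode *e* with bounding window *b* and 100 ms inner
   windows, on the difference wave `ERP(Probe) − ERP(Irrelevant1)`:

   `p2p_e = max_{w ⊆ b} mean(w) − min_{w' ⊆ b, w' after w*} mean(w')`

   the highest inner-window mean minus the lowest mean over windows starting
   at or after the first non-overlapping position that follows the highest
   window *w**. P3a parameters at Fz and Cz (bounding 150–1000 ms, highest
   peak constrained to end by 300 ms); P3b parameters at Pz (300–1000 ms,
   no cap).
2. **Randomise.** With m the smaller number of valid trials of the two
   conditions, m trials are drawn from each, pooled, and repeatedly
   relabelled into two m-sized surrogate groups; the surrogate `p2p_e`
   values (B = 1000 relabellings, shared across electrodes so
   within-trial cross-electrode correlation is preserved) form the null.
   `p_e = #(null > observed)/B`. Because the window search re-optimises on
   every resample, this is a maximal-statistic test: the liberal window
   placement needs no multiple-comparisons correction.
3. **Combine.** Each resample's statistics are converted to per-electrode
   p-values against their own null columns and scored with Fisher's
   combining statistic `−2 Σ ln p` (zeros replaced by the smallest
   legitimate value 1/B); the observed score's position in the B null
   scores gives the combined p, and `fisher_p < 0.05` is the detection
   decision.

Supporting analyses: intrinsic type-I-error calibration on fabricated null
datasets drawn from distractor-locked epochs, a six-ordered-pair null
screen over three irrelevant conditions, early–late vs even–odd repetition
controls, group paired contrasts, and a pooled fixed-effects latency
difference randomisation. A synthetic RSVP-EEG generator (1/f + alpha
background, two-Gaussian component templates) provides all of the above
with known ground truth.

## Worked example

```r
library(citerp)

cfg <- synth_profile("guilty", seed = 11)  # own-name P3a + P3b injected
es  <- simulate_subject(cfg)               # 50 trials/condition, Fz/Cz/Pz
det <- cit_detect(es, B = 1000, seed = 42)
det
#> Single-subject concealed-information detection
#>   subject: S01   m = 49 matched trials, B = 1000 resamples
#>   Fz  observed p2p =   11.579 uV   p = <0.001
#>   Cz  observed p2p =    9.107 uV   p = <0.001
#>   Pz  observed p2p =    9.993 uV   p = <0.001
#>   Fisher combined p = <0.001  =>  DETECTED at alpha = 0.05
```

One Probe trial was rejected by the ±50 µV artifact screen (so m = 49).
Every per-electrode p is below the 1/B floor — none of the 1000 surrogate
relabellings produced a peak-to-peak value above the observed one — and the
combined decision is positive. On a `"null"` profile subject the same call
returns p-values spread over (0, 1) and no detection; calibration can be
checked directly:

```r
esn  <- simulate_subject(synth_profile("null", seed = 3))
pool <- subset_trials(esn, esn$trials$condition == "distractor")
intrinsic_fp_rate(baseline_correct(pool), R = 100, B = 200, seed = 9)
#> Intrinsic validity run: R = 100 fabricated null datasets, B = 200, alpha = 0.05
#>            Fz    Cz    Pz Fisher
#> FP rate 0.050 0.040 0.070  0.060
#> Avg p   0.521 0.546 0.462  0.532
```

False-positive rates sit at the nominal 0.05 (up to binomial noise at
R = 100) and mean null p-values near 0.5.

## Layout

- `R/` — epoch container and TSV/JSON I/O, preprocessing, ERP averaging,
  peak statistics, randomisation + Fisher core (`cit_detect()`),
  group-level analyses, validity simulation, synthetic generator, CLI.
- `vignettes/detection-methodology.Rmd` — model, assumptions, parameter
  choices, generator realism and limitations.
- `tests/testthat/` — unit, property and oracle-equivalence tests plus the
  end-to-end calibration checks.
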