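Package: citerp
Title: Single-Subject P300 Concealed-Information Detection from RSVP EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Peak-to-peak P3a/P3b statistics on condition difference waves of
    epoched EEG, per-electrode randomisation tests with maximal statistics,
    and Fisher combination across electrodes, yielding per-individual
    detection of concealed-salient stimuli (e.g. the subject's own name) in
    rapid serial visual presentation streams. Includes baseline correction
    and amplitude-based artifact rejection, group-level paired contrasts,
    early-late and even-odd control analyses, fixed-effects latency
    difference randomisation, intrinsic-validity (type-I error) simulation
    on fabricated null datasets, and a synthetic RSVP-EEG generator with
    1/f-plus-alpha background noise for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
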