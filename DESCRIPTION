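Package: twinsync
Title: Pairwise Physiological Synchrony in Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying inter-subject physiological synchrony in
    dyadic (twin) cohorts across repeated meditation sessions. Implements
    beat-to-beat-interval (BBI) artifact detection and correction with
    time-varying quantile thresholds, shape-preserving (PCHIP) resampling of
    tachograms to a uniform 1 Hz series, sliding-window Pearson similarity and
    absolute-difference statistics under four pairing schemes (co-twin,
    dizygotic, twin-control, cross-pair), Wilcoxon and mixed-effects group
    comparisons, a Morlet-wavelet EEG band-power pipeline with pooled epoch
    rejection and coarse time-course extraction, a sham-pair bootstrap null
    with topographic masking, and a synthetic dyadic-cohort generator with
    known ground-truth coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
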