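Package: ecogposture
Title: Sensorimotor Beta and Gamma Bandpower Dynamics During Speech and
    Inter-Utterance Posture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electrocorticographic (ECoG) recordings of
    consonant-vowel speech production, centred on the dynamics of sensorimotor
    beta (12-35 Hz) and gamma/high-gamma (35-140 Hz) bandpower across speech
    movements and the inter-utterance speech posture (ISP) held between
    utterances. Provides a synthetic multi-channel ECoG generator with known
    per-sub-band event-related desynchronization/synchronization envelope
    structure; common-average referencing with bad-channel exclusion; notch
    and zero-phase Butterworth sub-band filtering; Hilbert analytic bandpower;
    trial epoching with inclusion rules, periodic-sinc interval normalization,
    per-session z-scoring and grand averaging; and inference tools:
    interval-wise Pearson correlation grids with Bonferroni control, local
    extrema and Gaussian-wavelet maps, PELT change-point detection under a
    modified BIC penalty, and linear mixed-effects interval models with
    likelihood-ratio tests and Tukey post hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    emmeans,
    jsonlite,
    lme4,
    signal,
    stats,
    utils,
    yaml
Suggests:
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
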