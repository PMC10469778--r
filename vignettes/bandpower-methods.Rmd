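---
title: "Sensorimotor bandpower dynamics across speech and inter-utterance posture: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensorimotor bandpower dynamics across speech and inter-utterance posture: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogposture)
```

## The scientific question

During speech, the vocal tract alternates between transient movements
(consonant and vowel gestures) and a tonically maintained inter-utterance
speech posture (ISP) — the resting configuration articulators hold between
utterances. In sensorimotor cortex, gamma-band activity (35--140 Hz) is the
established correlate of transient movement, while beta-band activity
(12--35 Hz) increases at movement termination and during steady-state
maintenance ("beta rebound") and decreases around movement onset
(event-related desynchronization, ERD). `ecogposture` implements an
analysis pipeline for electrocorticographic (ECoG) recordings of
consonant-vowel (CV) syllable production that quantifies these dynamics:
per-sub-band instantaneous bandpower over ISP1--CV--ISP2 trials, their
correlation structure, change-point segmentation of the averaged time
courses, and mixed-effects inference over the segmented intervals.

Because the motivating recordings are hours of multi-channel data, the
package pairs the pipeline with a synthetic ECoG generator whose
event-related envelope structure is known exactly, so every stage can be
validated by parameter recovery at desk scale.

## Signal model and processing chain

Each analyzed channel is band-passed into six logarithmically scaled
sub-bands: beta (12--21, 21--35 Hz), gamma (35--50, 50--70 Hz) and
high-gamma (70--99, 99--140 Hz). The chain, in order:

1. **Channel selection** — sensorimotor (SMC) channel indices minus the
   session's bad-channel list (`select_channels()`), then common average
   referencing over the surviving channels only
   (`common_average_reference()`). Referencing after exclusion matters: the
   simulated bad channels carry large low-frequency artifact that would
   otherwise leak into every channel through the common average.
2. **Epoching** (`build_trials()`) — trials are ISP1--consonant--vowel--ISP2
   sequences derived from speech start / CV-transition / end annotations,
   with gaps between utterances giving the ISP intervals. Inclusion rules,
   applied in a fixed order so exclusion tallies are unambiguous: boundary
   trials (first/last utterance) are dropped; trials intersecting annotated
   invalid intervals are dropped; only syllables whose final vowel is /i/
   are kept; both flanking ISPs must be at least 500 ms. Kept ISPs are
   clipped to the 500 ms nearest the CV interval, and 500 ms pads are
   attached on each side purely to absorb filter and Hilbert-transform edge
   effects.
3. **Filtering** (`notch_line_noise()`, `bandpass_subband()`) — line noise
   is removed with second-order IIR notches at 60/120/180 Hz, each applied
   forward-backward. The notches use a constant 2 Hz absolute bandwidth
   (quality factor 30 at the fundamental): a constant *relative* bandwidth
   would widen the 180 Hz notch to 6 Hz and dent the passband near the
   upper high-gamma band edge. Sub-band filters are 3rd-order Butterworth
   band-passes applied forward-backward (zero-phase, 6th-order magnitude).
4. **Bandpower** (`analytic_power()`) — the squared modulus of the analytic
   signal $x(t) + i\,\mathcal{H}[x](t)$, computed per trial epoch with the
   pads attached. For a sinusoid of amplitude $A$ this equals $A^2$; for
   narrowband noise it tracks the squared envelope. Per-channel power is
   averaged over the $N_{channels}$ valid SMC channels, and low/high
   sub-band pairs are averaged into merged beta, gamma and high-gamma
   bandpower.
5. **Time normalization** (`assemble_timecourse()`) — pads are discarded;
   consonant and vowel segments are resampled to the canonical average
   lengths (107 ms and 388 ms) by frequency-domain (periodic-sinc)
   interpolation; ISPs stay at 500 ms. Segment sample counts are
   `round(duration * fs)`, so at 3052 Hz the canonical trial is
   1526 + 327 + 1184 + 1526 = 4563 samples. Resampling is applied after pad
   truncation, so convolution edge effects never enter the canonical
   window.
6. **Standardization** (`zscore_session()`) — per session and band, power
   is z-scored against the pooled mean and SD over all samples of all
   included trials (we read "average session trial bandpower and standard
   deviation" as pooled-sample moments; trial-mean moments differ only by
   a scale factor under the canonical fixed-length design). Session means
   are then averaged into grand time courses with an across-session
   standard error (`grand_average()`); $\sigma/\sqrt{N}$ is the default,
   with $\sigma/N$ available as an option for compatibility with reports
   that print the latter convention.

## Inference

**Correlation grids.** Pearson correlations between all 15 sub-band pairs
are computed over the samples of each canonical interval of the
grand-average time courses, with two-tailed p-values and a Bonferroni
threshold $\alpha/m = 0.05/15 \approx 0.003$. Correlations on the
grand average (rather than pooled trial samples) are the default because
the trial-level envelope noise is band-dependent and would attenuate
pairwise correlations unevenly; the grids are invariant to the per-band
affine freedom left by z-scoring. A CV-transition-centred window variant
(`cv_centered_correlations()`, one canonical consonant length wide by
default) probes local coupling at the consonant--vowel transition.

**Extrema and wavelet maps.** Strict interior local maxima/minima per
interval (`local_extrema()`) and a Gaussian-template correlation map
(`gaussian_wavelet_map()`): zero-mean, unit-energy Gaussian templates with
standard deviations 1--42 samples (support truncated at $\pm 4\sigma$)
correlated with the series at every lag. Positive coefficients mark
peak-like features at that scale, negative ones troughs; constants map to
zero because the templates are zero-mean.

**Change points.** `detect_change_points()` segments each grand time
course with PELT under a normal mean-shift cost and a modified BIC
penalty: on the $-2\log L$ scale each segment costs
$\mathrm{RSS}/\sigma^2 + \log(\ell/n)$ and each change point
$3\log n$ (the Zhang--Siegmund mean-shift MBIC). The pruning constant
$K = \log n$ bounds the subadditivity defect introduced by the
segment-length term, so the pruned search remains exact — the test suite
checks equality with an exhaustive dynamic program on hundreds of random
series. The minimum segment length is 10 canonical samples. The noise
scale $\sigma$ defaults to a difference-based MAD estimate (appropriate
for white noise); the pipeline passes the grand-average standard error
instead, because grand-averaged envelope noise is temporally correlated
over roughly the envelope correlation time (~100 ms) and a
difference-based estimate would be badly biased downward, producing
segmentations that chase noise wiggles.

**ERD onset.** The onset of the pre-movement beta decline is estimated by
`erd_onset()` as the right edge of the maximum-mean change-point interval
at or before consonant onset — i.e. the boundary where the series leaves
its pre-movement maximum, the direct analogue of comparing the first two
segmented intervals. A raw "first change point" is not a faithful
estimator here: the Hilbert envelope of a 14 Hz-wide band has ~70 ms
intrinsic time resolution, and early ISP1 legitimately contains the tail
of the preceding trial's beta rebound, both of which displace the first
boundary.

**Interval models.** For each sub-band, per-session mean power within each
change-point interval (one observation per session per interval) enters a
linear mixed-effects model with a fixed interval effect and random session
intercepts, fitted by maximum likelihood (`interval_lme_lrt()`); REML
likelihoods are not comparable across fixed-effect structures, so ML is
required for the chi-squared likelihood-ratio test against the null model
without the interval predictor ($df = K - 1$). Singular random-effect fits
are flagged, never silently dropped. Post hoc, all pairwise interval
contrasts are Tukey-HSD adjusted (`tukey_pairwise()`); "Bonferroni-
corrected pairwise Tukey test" is ambiguous (Tukey HSD is itself a
family-wise correction), so both stages are reported separately: the Tukey
adjusted p-value, and a second-stage Bonferroni factor across the six
band-wise families. Satterthwaite degrees of freedom are used when the
interval count is modest ($K \le 12$); for larger segmentations the
asymptotic z approximation is used, since Satterthwaite costs grow
quadratically in the number of contrasts and the per-cell replication
already makes the two nearly identical.

## The synthetic generator

`generate_session()` emulates the *shape* of a CV-syllable reading
session: multi-channel cortical surface potentials at a configurable rate
(1000 Hz by default — all analysis bands sit below 140 Hz, so tests need
not pay for the original 3052 Hz; that rate remains configurable), with
per-utterance annotations and invalid intervals. Each good channel is

$$x_c(t) = \sum_{b=1}^{6} E_b(t)\, w_{c,b}(t) + n_{1/f}(t) + \ell(t),$$

where $w_{c,b}$ is unit-RMS band-limited Gaussian noise (narrowband noise,
not a pure tone, so its Hilbert envelope behaves like real cortical
bandpower), $E_b$ the band's piecewise-linear event envelope, $n_{1/f}$
pink noise, and $\ell$ 60/120/180 Hz line noise with a random per-channel
gain (a common gain would be cancelled exactly by the common average
reference, which would make the notch stage untestable). Bad channels are
replaced by large low-frequency artifact that only exclusion can remove.

The envelopes encode the qualitative event sequence of sensorimotor
bandpower around a syllable: beta holds a high ISP plateau, declines from
400 ms before consonant onset to a minimum early in the vowel, rises to a
local peak before vowel termination, dips briefly at termination and
rebounds to the plateau; gamma/high-gamma mirror this with a 300 ms
pre-onset rise lead and a peak near the CV transition (mid-vowel for low
gamma, which also shows the brief post-termination spike). Node levels are
in arbitrary units; power follows the squared envelope. When utterance
gaps are short, the post-termination rebound is compressed so that the
*next* trial's pre-onset lead node keeps its anchored time — the lead is
the quantitative event the pipeline must recover, the rebound time
constant (250 ms) is not. Defaults draw utterance gaps from U(500, 1150) ms
(median ~825 ms), consonant lengths from U(60, 160) ms and vowels from
U(250, 530) ms, with a third of syllables ending in /i/, eight channels
and one bad channel — a 10-session collection then yields roughly 50
included trials per session. The paper-scale deposited recordings give no
amplitude calibration for these envelopes, so levels were chosen for
testability (clear ERD/ERS contrast at realistic trial counts), not for
biophysical realism.

What passing recovery tests on this generator shows: the pipeline's
filtering, epoching, normalization, averaging and segmentation stages are
numerically faithful — a known envelope structure survives the whole chain
(grand time courses correlate > 0.9 with the squared templates, the
400 ms beta ERD lead is recovered within ±50 ms, and beta/high-gamma
anti-correlation signs are recovered in all four intervals). What it does
not show: anything about real cortical dynamics — the generator has no
somatotopy, no cross-channel correlation structure, no amplitude realism,
and its events are piecewise-linear caricatures.

## Numerical choices and degenerate inputs

* Sample-count rounding is `round(duration * fs)` (ties to even)
  everywhere, fixing a deterministic canonical grid.
* Analytic signals are computed per padded epoch; the first/last 100 ms of
  any analytic series are considered unreliable, and the 500 ms pads more
  than absorb that margin.
* Frequency-domain resampling preserves constants exactly and returns the
  input unchanged when the target length equals the input length.
* Zero-variance inputs error loudly: z-scoring a constant session,
  correlating a constant band, referencing a single channel and resampling
  length-1 series are all rejected rather than silently propagated.
* All simulation randomness flows from explicit integer seeds;
  `run_pipeline()` derives per-session seeds from the master seed, and the
  report's provenance block records the seed and a configuration hash.
* The fixture format is deliberately plain text (JSON + CSV) so fixtures
  are diffable and portable; there is no binary container dependency. The
  `cli_report` surface is the pair `pipeline_config()` / `run_pipeline()`
  (plus `load_pipeline_config()` for YAML/JSON configs): users of an
  analysis package drive it from R, so no shell wrapper is shipped.

## Problem sizes

Unit tests run the pipeline on a 3-session, 4-channel collection of
40-utterance sessions; the end-to-end acceptance checks use the default
10-session, 8-channel collection (~155 utterances, ~50 included trials per
session) and a 1000-replicate null calibration of the interval LRT
(31 sessions x 5 intervals, matching the session count of the motivating
dataset). These sizes were chosen so the full validation cycle completes
in minutes on a single core while keeping every stage's statistics
comfortably away from small-sample artifacts.

## Known limitations

* No NWB reader: sessions enter either through the synthetic generator or
  through the plain-text fixture dialect. Ingest of the original deposited
  recordings would need an external conversion step.
* Correlation p-values treat interval samples as independent; the
  grand-average series are strongly autocorrelated, so these p-values are
  descriptive (as is conventional for this analysis), and the Bonferroni
  threshold controls only the pairwise-family error.
* The mean-shift segmentation treats the grand time course as piecewise
  constant plus white noise; with correlated envelope noise the MBIC
  penalty is only approximately calibrated, which is why the noise scale
  is supplied externally by the pipeline.
* `erd_onset()` assumes a single dominant pre-movement maximum; series
  with multimodal pre-onset structure would need the full interval table
  instead.
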