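---
title: "Methods: the facial sEMG affect pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the facial sEMG affect pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(faceemg)
```

`faceemg` analyses five-channel facial surface EMG (left/right orbicularis
oculi, left/right zygomaticus major, corrugator supercilii) recorded while
subjects watch affective videos and rate each one for valence and arousal on
a 1–9 scale. This vignette documents the model behind each stage, the
tunable parameters and their defaults, what the synthetic generator does and
does not emulate, and the numerical choices made where the design was
genuinely open.

## Signal model and denoising

Raw facial sEMG is a broadband (≈20–450 Hz) stochastic signal whose
short-time amplitude scales with muscle activation, contaminated by three
nuisance components: sub-20 Hz motion/blink/ocular artifacts, narrowband
mains interference at 50 Hz and its harmonics, and negligible content above
500 Hz. `denoise()` addresses them per channel, in a fixed order:

1. **Muscle-specific zero-phase high-pass.** Facial muscles carry genuine
   EMG power close to the artifact band, so the cutoff is per muscle: 30 Hz
   for the corrugator, 20 Hz for orbicularis and zygomaticus. The filter
   family and order are not dictated by the analysis convention we follow;
   we use a 4th-order Butterworth applied forward–backward
   (`signal::filtfilt`) — standard sEMG practice, monotone pass-band, zero
   net group delay, and ≥ 40 dB attenuation one octave beyond the cutoff
   for the effective 8th-order magnitude response.
2. **Spectrum-interpolation powerline suppression.** A notch filter would
   delete genuine EMG power at 50, 100, … Hz. Instead,
   `suppress_powerline()` replaces the *magnitude* of the FFT bins within
   ±0.5 Hz of each harmonic by a linear interpolation of the mean
   magnitudes of the flanking bands (1–3.5 Hz on each side, excluding other
   notch bands) while preserving every bin's phase, then reconstructs by
   inverse FFT. Harmonics are processed from 50 Hz up to the effective
   low-pass cutoff (450 Hz at fs = 1000).
3. **Zero-phase low-pass.** The nominal 500 Hz cutoff equals Nyquist at the
   study's 1000 Hz sampling rate and is unrealizable there; we use
   `min(500, 0.45 · fs)` — 450 Hz at 1000 Hz. Since sEMG power above
   450 Hz is negligible, this is conservative.

**Whole-recording versus segmented interpolation.** Spectrum interpolation
is applied to the whole recording in a single transform by default. We also
implement a half-overlapping Hann-windowed segmented mode (`segment_s`),
which can track slow drift of the interference amplitude; its replaced band
is automatically widened by the window's main-lobe width (2/`segment_s` Hz)
so a spectral line's leakage is covered. We measured, however, that a strong
*stationary* line leaves a coherent residual of several dB above the noise
floor in segmented mode — the replaced bins keep the line's phase in every
segment, so the overlap-add re-concentrates power at the line frequency —
whereas the whole-signal transform flattens it into the flanking floor and
additionally guarantees that bins outside the notch bands are untouched.
Whole-recording processing is therefore the default; use segments only for
visibly nonstationary interference.

## Amplitude extraction and normalization

`amplitude_envelope()` computes sliding-window RMS (default) or MAV.
Window and hop are open choices; the defaults are **250 ms windows every
50 ms** (20 Hz envelope rate): long enough to smooth over the EMG carrier,
short enough to track expression dynamics. Both are exposed so envelopes can
be matched to differently pre-processed data. RMS is the analysis measure;
MAV is provided for completeness and satisfies RMS ≥ MAV windowwise.

Because absolute sEMG voltage is not comparable across subjects or
electrode placements, envelopes are normalized per subject and channel over
the **whole session (breaks included)**:

- **Winsorization (5th/95th percentile, asymmetric).** Values below the 5th
  percentile are set to **0** (not to the percentile): sub-threshold
  activations are treated as noise. Values above the 95th percentile are
  clipped to it, suppressing bursts. The asymmetry is deliberate and
  implemented exactly as stated; a symmetric variant can be obtained via
  `winsorize_envelope()`'s percentile arguments if a sensitivity analysis
  needs it.
- **Min–max normalization** to [0, 1], with min and max taken from the
  winsorized envelope (so min is 0 whenever any value fell below the 5th
  percentile, and max is the 95th percentile whenever any value exceeded
  it). A constant (degenerate) channel maps to all zeros with a warning
  rather than an error, since one flat channel should not abort a cohort.

The five-sensor average is computed **after** normalization (the average of
normalized traces, matching how the montage average is displayed and
analysed alongside the sensors); computed before normalization it would be
dominated by whichever electrode has the largest raw voltage. The entire
chain is scale-invariant: multiplying a raw channel by any positive
constant leaves the normalized envelope unchanged to numerical precision,
which the test suite asserts at 1e-9.

## Epoching and condition means

`per_video_amplitude()` assigns an envelope sample to a video when its
window *start* lies in the half-open presentation interval
[start, end); with 10 s rating breaks a 250 ms window can never straddle
two videos. Per-subject condition means are **unweighted means over the
subject's videos** in a condition (not duration-weighted), for three
schemes: subjective-valence bins (ratings 1–4 = negative, 6–9 = positive,
the midpoint 5 excluded), subjective-arousal bins (1–4 low / 6–9 high), and
the predefined video type. Rating-*level* means (one value per subject per
level 1–9 that the subject actually used) feed the correlation and trend
analyses; pooling is per subject per level throughout.

Subjects can lack a rating bin entirely (e.g. no video rated 1–4). Such
subject/condition cells are flagged and the affected subjects are dropped
**pairwise** from the paired tests, so n can fall below the cohort size for
individual comparisons.

## Statistics

- **Friedman rank test** (`friedman_rank_test()`): within-subject mid-ranks,
  chi-square statistic with the standard tie correction, df = k − 1, plus
  the per-condition mean ranks. Used as the omnibus manipulation check on
  the self-reports; pairwise follow-ups run only when the omnibus test is
  significant at 0.05.
- **Wilcoxon signed-rank** (`wilcoxon_signed_rank()`): zero differences are
  discarded by default (the mainstream convention; Pratt's method is
  available). The p-value uses the exact signed-rank distribution when no
  ties remain and n ≤ 25, and the tie-corrected normal approximation
  (no continuity correction) otherwise. The reported `z` always comes from
  the normal approximation, signed so that `z > 0` when the first operand
  tends to exceed the second; each result row names its operand order.
- **Multiplicity.** Bonferroni within exactly the analysis families: m = 6
  for each rating-bin family (five sensors + average), m = 18 for video
  type (3 category pairs × 6 modalities). The manipulation-check follow-ups
  are reported uncorrected. Star annotations: `ns` for p > 0.05, `*` for
  (0.01, 0.05], `**` for (0.001, 0.01], `***` for (1e-4, 1e-3], `****` for
  p ≤ 1e-4 — i.e. smaller p earns more stars, with half-open bands.
- **V-shape quantification.** Pearson correlations of per-subject-per-level
  amplitude against valence level over the segments [1–5], [5–9] and
  [1–9] (inclusive bounds; the level 5 points belong to both limbs), and an
  OLS quadratic fit `value ~ level + level²` whose positive curvature is
  the V-shape signature; `trend_confidence_band()` provides the 95%
  confidence band shown by `autoplot()`.

## The synthetic cohort generator

`simulate_session()` emulates the study design: 38 subjects, 25 videos in
four fixed blocks (five neutral totalling 76 s, six negative/93 s, five
neutral/81 s, nine positive/78 s), 10 s rating breaks, five channels at
1000 Hz. Note the printed per-block durations sum to 328 s of video while
the protocol description also quotes a 338 s total; the generator follows
the per-block numbers, which are the ones that define the schedule.

Each channel is Gaussian white noise band-limited to 20–450 Hz (ideal
FFT-domain band-pass) whose envelope SD during a video is

```
baseline_sd × gain(muscle, category) × (1 + coupling(muscle) × (arousal − 5)/4)
```

with 100 ms raised-cosine transitions between videos (no edge ringing), plus
a 50 Hz sinusoid and harmonics (amplitude A/k for harmonic k, random phase)
and a sub-20 Hz artifact (a < 1 Hz random-walk drift plus Poisson-timed
200 ms biphasic blink pulses). Ratings are drawn per category from a
discretized truncated normal (round, clip to 1–9) with the per-category
means/SDs of the study's validated stimulus set — neutral 4.65 ± 1.11
valence / 3.41 ± 1.65 arousal; negative 3.18 ± 1.70 / 6.67 ± 1.40; positive
6.60 ± 1.26 / 5.88 ± 1.48. The arousal coupling is multiplicative on the
envelope SD, centred at the scale midpoint and scaled by 1/4 so a rating of
9 doubles a unit coupling — monotone, bounded, and easy to invert in tests.
A session is a pure function of (schedule, config, subject seed); cohorts
derive per-subject seeds deterministically from the cohort seed.

**Default effect profile.** The gains encode the qualitative group-level
pattern the pipeline should recover. Positive muscles: neutral 1.0 <
negative 1.5 < positive 2.5 (high at both valence extremes, lowest at
neutral — the V shape), with arousal coupling 0.25. Corrugator: negative
2.0 > neutral 1.49 > positive 1.0, coupling 0. The corrugator's neutral
gain is not arbitrary: it is calibrated so that the expected *normalized*
corrugator amplitude of videos landing in the low-arousal rating bin equals
that of the high-arousal bin under the default rating model. A first-order
balance in raw gain units ((6·g_neg + 9·g_pos)/15 weighted by the bin
occupancies the per-category arousal distributions imply) gives ≈1.56, but
the winsorization clip compresses the strongest (negative-video)
activations, so the balance must be computed on the normalized scale; a
root-find of the mean bin difference over a small gain sweep of simulated
cohorts lands at 1.49. The corrugator arousal contrast is thereby null *by
construction*, matching the phenomenology that corrugator activity does not
separate low from high arousal while staying relatively high for neutrally
valenced content.

**What the generator does not emulate:** motor-unit action-potential
physiology, electrode cross-talk between overlapping facial muscles,
habituation or order effects across the session, within-video dynamics,
rater idiosyncrasies beyond the category-conditional normal, and
nonstationary interference. Passing tests therefore demonstrate that the
pipeline recovers effects of the configured form at realistic SNR and
cohort size — not that real recordings are this well-behaved.

## Numerical choices and degenerate inputs

- Percentiles use R's default quantile definition (type 7).
- Envelope sample t summarizes the window starting at (t−1)·hop; envelope
  length is ⌊(N/fs − window)/hop⌋ + 1.
- Constant envelopes normalize to all zeros with a
  `faceemg_degenerate_channel` warning; all-zero paired differences raise a
  `faceemg_degenerate_comparison` condition which the family tables report
  as a `note` rather than aborting; paired cells with fewer than 5 complete
  pairs are likewise reported, not fatal.
- The quadratic fit refuses fewer than 4 points or fewer than 3 distinct
  levels (rank deficiency); segment correlations refuse fewer than 3 points
  or zero variance.
- Friedman's tie correction degenerates to chi2 = 0 for an all-constant
  matrix.

## Problem sizes used by the test suite

The suite exercises the full-scale study configuration once (38 subjects ×
5 channels × 1000 Hz × ~578 s sessions) for the effect-recovery check, and
uses reduced sizes elsewhere as a deliberate design choice: oracle
comparisons run on hundreds of small random instances; type-I error control
uses 200 replicate null cohorts of 15 subjects × 6 videos at 250 Hz with a
20–100 Hz carrier (the statistical properties under test do not depend on
the sampling rate); exploratory cohorts in examples use 6–8 subjects at
250 Hz. The familywise error bound is checked against
0.05 + 2 Monte-Carlo standard errors over the 200 replicates.

## Known limitations

- The five-sensor average is averaged after normalization; analyses that
  average raw voltages are not comparable.
- Envelope window/hop and the interpolation notch/flank widths are
  conventions, not identified from data; matching independently
  pre-processed datasets may require adjusting them.
- The pipeline is group-level and offline: no real-time processing, no
  per-subject affect classification, no mixed-effects modelling of the
  repeated measures beyond the rank tests.
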