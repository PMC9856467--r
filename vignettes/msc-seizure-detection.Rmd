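---
title: "Multi-site seizure detection from coherence maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site seizure detection from coherence maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscdetect)
```

## The detection problem

In chronic epilepsy models (and in intracranial monitoring generally), a
seizure onset is accompanied by an abrupt increase in *synchronization*
between recording sites, often confined to a subject-specific frequency
band: some subjects express the change in a high-frequency band
(e.g. 150–450 Hz between hippocampal sites), others at low frequencies
(1–30 Hz across hemispheres). A detector built on a fixed band and fixed
channels therefore underperforms. `mscdetect` implements a two-stage
method:

1. **Preprocessing (individualization).** For every channel pair, a
   magnitude-squared coherence (MSC) map — coherence spectra in sliding
   400 ms windows, spliced into a time × frequency image — is scanned with a
   Canny-style edge detector. The edges mark where and in which band
   coherence jumps at seizure onset. Pairs are ranked by the summed map
   values at their edge pixels around annotated onsets; the top pairs and
   the intersection of their edge bands define the *detection channels* and
   the *detection band*.
2. **Detection (cheap online stage).** The selected channels are band-pass
   filtered to the detection band (zero-phase), and the maximal normalized
   cross-correlation is computed in the same sliding windows. Two feature
   curves drive detection: **AVG**, the mean of the selected pairs'
   correlations (overall synchronization), and **STD**, the standard
   deviation over the selected *plus* ten non-reactive "background" pairs.
   A genuine multi-site event raises AVG and spreads the pooled values
   apart (high STD); common-mode artifacts move all pairs together and
   leave STD low, which is why both thresholds must fire (logical AND).

Thresholds follow `Th = u + 3·sd`, with `u` and `sd` the mean and
population standard deviation of each feature curve over a training span,
and are periodically re-verified: if any seizure in a verification block is
missed, or the false-alarm rate exceeds 10/h, thresholds are recomputed
from that block's curves and adopted only if they then detect everything in
the block.

## Estimators and numerical choices

**Welch MSC.** Within each 400 ms window (400 samples at 1 kHz), coherence
`C_xy(f) = |P_xy|² / (P_xx P_yy)` is estimated by Welch's overlapped
averaged periodogram: 8 Hamming-tapered, mean-detrended subsegments with
50 % overlap (subsegment length ⌊400/4.5⌋ = 88 samples), zero-padded to a
256-point FFT. A single full-window periodogram would make the ratio
identically 1; averaging is what gives the estimator its power to
discriminate. The window length sets the map's nominal resolution floor at
1/0.4 s = 2.5 Hz; the subsegment layout trades resolution (≈3.9 Hz bins,
reliable above ~11 Hz) for variance reduction, and is exposed in
`spectral_config()` for users who want a different trade. Degenerate
zero-variance segments are an error in the scalar estimator and map to 0
in batch map construction.

**Edge detection.** The map is smoothed with a sampled 2-D Gaussian
(σ = 2 px, truncated at ±⌈4σ⌉, symmetric border padding), differentiated
with 2×2 averaged finite differences, thinned by non-maximum suppression
along the gradient direction quantized to four axes (ties kept, so plateau
ridges survive), and linked by dual-threshold hysteresis: the high
threshold is 0.90 of the *maximum normalized* gradient magnitude, the low
threshold 0.4× the high, weak pixels kept only when 8-connected to a
strong pixel. Normalizing by the per-map gradient maximum makes the 0.90
fraction meaningful across maps whose absolute contrast differs. The
gradient direction is `atan2(Gy, Gx)`; suppression along anything other
than the true gradient direction would erase legitimate edges.

**Pair scoring and band.** Scores are summed over the training onsets
within a 5 s window (±2.5 s) around each onset. A pair's band is the
frequency extent of the *principal* (strongest) 8-connected edge component
— pooled across training onsets, because a single onset's component can
fragment under suppression, and the union over five onsets is a much more
stable estimate of the reactive band. The common detection band intersects
the bands of selected pairs whose accumulated edge strength reaches at
least half the top score: on synthetic ground truth the edge-bearing pairs
score 3–4× above the strongest noise pair, so the 50 % screen cleanly
separates pairs that carry band information from pairs whose "edges" are
noise. If the strict intersection is empty, the longest frequency run
covered by at least half of the bands is used; only when that too is empty
does band selection fail over to manual entry. The QCCS score (sum of all
map pixels within ±2.5 s of the detected edge, 0–500 Hz) is kept as a
separate quantity for channel-by-channel synchronization matrices and
stability monitoring.

**Cross-correlation.** `R_xy(n) = (1/N) Σ x(m) y(m+n)` is the biased
estimator with zero padding outside the window, normalized by
`√(R_xx(0) R_yy(0))` and maximized over lags |n| ≤ 50 ms. The 50 ms bound
is not part of the published procedure; it is chosen to cover
physiological conduction delays while staying far below the window length
(an unbounded search maximizes over pure noise at extreme lags) and is
exposed in `cc_curves()`. The maximum is taken over *signed* values:
anti-phase coupling scores low by design. Band-passed inputs are zero-mean,
so no centering term is applied — consistent with the estimator above.
Zero-energy windows return 0 (no synchrony evidence). The implementation
evaluates all windows at once through FFT cross-correlation and is verified
against a direct double-loop oracle.

**Thresholding.** The training span for `Th = u + 3·sd` runs from the
start of the features through the offset of the fifth seizure, i.e. it
includes the interictal background *and* the training seizures. Computing
`u` and `sd` over ictal windows alone would place the threshold above every
ictal value and make detection impossible; including the background places
it between the baseline and ictal levels, which is also the only reading
consistent with reported thresholds far below ictal feature values.
Population (1/N) standard deviations are used throughout. Detection uses a
single-window AND of the two thresholds (no multi-window persistence — the
method's sub-second delays are incompatible with persistence rules), with
a 30 s refractory absorption after each event. Evaluation matches each
event to the first unmatched annotation whose onset lies within 60 s
before the event; refractory and match windows are operational constants
exposed in the API.

## The synthetic generator

`synth_config()` / `synth_lfp()` emulate exactly the statistical structure
the method assumes, and nothing more:

* independent 1/f^α Gaussian background per channel (α = 1, SD 50 µV —
  a standard spectral model for LFP background);
* during each annotated epoch, one shared source per epoch — white noise
  FFT-masked to the coupling band (sharp band edges, so the reactive band
  is well defined) — added to every coupled channel with a fixed
  per-channel gain (0.8–1.2×) and fractional-sample lag (≤ 5 ms, exact FFT
  phase-ramp delay), exercising the lag search;
* optional common 50 Hz mains and 16-bit quantization.

The standard validation recording is 12 channels at 1 kHz for 30 minutes
with fifteen 10 s seizures every 120 s; the first five train the selection
and thresholds. Coupling is confined to the three pairs of a three-channel
clique — channels 1–3 — so that exactly three pairs are genuinely coupled
(a shared source among channels of *disjoint* pairs would couple every
cross pair too), in the 150–250 Hz band at gain 4× the background SD
(strong coupling, the regime the preprocessing stage is designed for).

What the generator does **not** model: postictal suppression, nonstationary
background, electrode artifacts, seizure-to-seizure variability of the
reactive band, volume-conduction common signals, and real seizure
morphology. Passing the end-to-end checks therefore demonstrates that the
implementation recovers planted structure under the method's own
assumptions — not clinical-grade performance on animal or human data,
whose headline numbers cannot be reproduced without those recordings.

```{r example, eval = FALSE}
sim <- synth_lfp(synth_config(seed = 1))
sel <- select_pairs(sim$recording, sim$annotations,
                    spectral_config(f_max = 500), n_train = 5)
feats <- avg_std(cc_curves(sim$recording,
                           rbind(sel$selected, sel$background),
                           band = sel$band),
                 sel$selected, sel$background)
th <- init_thresholds(feats, sim$annotations, n_train = 5)
evaluate_detections(detect_events(feats, th), sim$annotations,
                    sim$recording$duration_s)
```

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `window_s` / `overlap_s` | 0.4 / 0.2 | s | map and feature grid; 2.5 Hz window resolution floor |
| `welch_n_sub` / overlap | 8 / 0.5 | – | variance/resolution trade inside a window |
| `sigma` | 2 | px | edge-detector smoothing scale on the map grid |
| `high_threshold`, `low_ratio` | 0.90, 0.4 | – | hysteresis levels on the normalized gradient |
| onset window | ±2.5 | s | scoring span around an annotated onset |
| `n_select` / `n_background` | 10 / 10 | pairs | detection set and STD stabilizer set |
| `band_min_frac` | 0.5 | – | screen for band-carrying pairs before intersection |
| `max_lag_ms` | 50 | ms | lag search bound (≈ conduction delays) |
| training seizures | 5 | – | initial threshold span |
| `far_bound` | 10 | /h | verification rule for threshold retention |
| `refractory_s` / `match_window_s` | 30 / 60 | s | event absorption and evaluation matching |

## Degenerate inputs and tie rules

Zero-variance segments, empty pair sets, onsets outside a map's span, and
zero-duration recordings raise errors naming the violated precondition.
All-zero gradient maps produce empty edge sets without dividing by the
maximum. Ranking ties break deterministically by channel indices; NMS
keeps ties (`≥`) so uniform plateaus are not erased. With fewer than 20
pairs, the background set takes the lowest ⌊n/2⌋ pairs not already
selected.

## Problem sizes used in validation

The shipped checks run on desk-scale instances chosen as the smallest
sizes that still exercise every stage meaningfully: the 30-minute /
12-channel standard recording for the end-to-end check (selection on five
onsets, 66 pair maps per onset; ~9000 feature windows over 20 pairs),
360 s four-channel blocks for the threshold-iteration scenario, 20
synthetic step maps for edge localization, and 50-instance oracle
batteries for the estimators.

## Known limitations

* The Welch layout inside a 400 ms window cannot genuinely resolve the
  nominal 2.5 Hz floor; band edges below ~11 Hz are blurred across bins.
* Band selection assumes the reactive band is contiguous; multi-band
  seizures would be truncated to the strongest component's extent.
* Anti-phase coupling is invisible to the signed correlation maximum.
* The online stage reuses the initially selected pairs; slow migration of
  the epileptogenic network is handled only through threshold
  re-verification, not re-selection (re-running `select_pairs()`
  periodically is the intended remedy).
* EDF support is read-only and requires a uniform sampling rate across
  signals.
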