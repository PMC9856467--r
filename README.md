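# mscdetect

Seizure-onset detection for multichannel intracranial EEG / local field
potential recordings, built on **multi-site synchronization changes**.

Seizures in chronic epilepsy models announce themselves as an abrupt
increase in synchronization between recording sites, confined to a
frequency band and a set of channel pairs that differ between subjects.
`mscdetect` individualizes the detector in a preprocessing stage and then
runs a cheap online stage:

1. **Preprocessing.** For every channel pair a magnitude-squared-coherence
   (MSC) map — Welch coherence spectra

   `C_xy(f) = |P_xy(f)|² / (P_xx(f) · P_yy(f)) ∈ [0, 1]`

   in sliding 400 ms windows (200 ms overlap) — is scanned with a Canny
   edge detector (Gaussian σ = 2, non-maximum suppression, hysteresis at
   0.90 / 0.36 of the maximal normalized gradient). Pairs are ranked by the
   sum of map values at their edge pixels in a ±2.5 s window around
   annotated onsets; the top-10 pairs and the intersection of their edge
   frequency bands become the detection channels and detection band.
2. **Detection.** The selected channels are zero-phase band-passed to the
   detection band; in each 400 ms window the maximal normalized
   cross-correlation `max_n R̂_xy(n)/√(R̂_xx(0)R̂_yy(0))` (|lag| ≤ 50 ms) is
   computed per pair. Detection features are **AVG** (mean over selected
   pairs) and **STD** (standard deviation over selected + 10 background
   pairs); an onset fires where both exceed their thresholds
   `Th = u + 3·sd`, initialized on the first five seizures and re-verified
   block by block (recomputed when a seizure is missed or the false-alarm
   rate exceeds 10/h).

A synthetic LFP generator (`synth_lfp()`) with per-channel 1/f background
and a shared band-limited source during labeled epochs makes the whole
chain testable with known ground truth. Comparison baselines (mean phase
coherence, plain cross-correlation, and seven standard single-channel
features) plug into the identical threshold machinery.

Intended users: electrophysiology labs running long-term seizure
monitoring in animal models, and anyone studying band-specific
synchronization changes in multichannel LFP/iEEG.

## Worked example

```r
library(mscdetect)

sim <- synth_lfp(synth_config(seed = 1))   # 12 ch, 30 min, 15 seizures
sim$recording
#> <lfp_recording> 12 channels x 1800000 samples @ 1000 Hz (1800.00 s)

sel <- select_pairs(sim$recording, sim$annotations,
                    spectral_config(f_max = 500), n_train = 5)
sel
#> <selection_result> band 132.8-265.6 Hz; 10 selected, 10 background pairs
#>   top pairs: 1-3 2-3 1-2 3-8 1-6

feats <- avg_std(cc_curves(sim$recording,
                           rbind(sel$selected, sel$background),
                           band = sel$band),
                 sel$selected, sel$background)
th <- init_thresholds(feats, sim$annotations, n_train = 5)
th
#> <thresholds> AVG 0.4445 (u=0.2446, sd=0.0666); STD 0.2624 (u=0.0617, sd=0.0669) [init]

evaluate_detections(detect_events(feats, th), sim$annotations,
                    sim$recording$duration_s)
#> <eval_report> detection rate 100.00% (15/15), FAR 0.00/h, mean delay 0.09 s
```

The generator plants coupling on the three pairs among channels 1–3 in the
150–250 Hz band; the selection stage recovers exactly those pairs at the
top of the ranking and a band overlapping the planted one, and the
threshold detector then finds every seizure with no false alarms and
sub-second delay. `vignettes/msc-seizure-detection.Rmd` documents the
model, the estimators, every tunable parameter, and what the synthetic
conditions do and do not demonstrate.

File I/O: CSV/RDS recordings (`read_recording()`, `write_recording()`),
read-only EDF, annotation CSVs, JSON selections/thresholds, CSV feature
curves. A thin command-line wrapper with `simulate` / `select` /
`features` / `detect` / `evaluate` subcommands is installed at
`inst/cli/mscdetect`.

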