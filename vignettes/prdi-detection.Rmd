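---
title: "Detecting post-regurgitation deep inhalation from nostril thermography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting post-regurgitation deep inhalation from nostril thermography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prditherm)
```

## The problem

Rumination is a sensitive welfare and health indicator in cattle, but the
established detection methods (noseband pressure sensors, accelerometers,
microphones) all require hardware mounted on the animal. A fully non-contact
alternative is to watch the animal breathe through an infrared camera: the
nostril region cools when ambient air is inhaled and warms when body-warm air
is exhaled, so the mean temperature over a segmented nostril region
oscillates with respiration. Each regurgitation of a feed bolus is
accompanied by a brief apnea (the glottis closes while the bolus travels)
followed by a compensatory deep inspiration. That **post-regurgitation deep
inhalation (PRDI)** appears as an unusually deep minimum in the
nostril-temperature breathing signal, and separating PRDI from ordinary
inhalations (**NRI**, non-rumination inhalation) is what this package
implements, end to end: signal extraction, breath-event detection, event
labeling, a depth-threshold classifier, and its full statistical evaluation.

The package does not segment nostrils itself — segmentation is a separate
computer-vision task whose output (binary masks per frame, possibly at RGB
resolution) is one of the accepted inputs. A seeded simulator produces
ground-truthed recordings with the same structure, so the whole chain is
testable without any footage.

## The signal chain

Starting from a uniformly sampled nostril temperature series $x(t)$ (default
8.7 samples/s, the frame rate of the intended acquisition setup):

1. **Band-pass filter.** Calf respiration spans roughly 0.2–1.0 Hz (12–60
   breaths/min). A 3rd-order Butterworth band-pass with exactly those edges
   removes baseline drift (ambient changes, camera distance) and
   high-frequency noise. The filter is applied forward–backward so it has
   *zero phase*: a group delay would systematically shift event times and
   bias the 3-second window assignment below. Edges are padded by odd
   (point-symmetric) reflection, three low-edge cycles long, and the padding
   is trimmed afterwards; the mean is removed first, so a constant input maps
   to exactly zero.
2. **Z-score standardization.** Per recording (per segment, see below), the
   filtered signal is centred and scaled to unit sample standard deviation
   ($n-1$ denominator; at these lengths the population/sample distinction is
   under 1%). This removes the scale differences between recordings caused by
   ambient temperature, individual animals, and camera distance, which is
   what makes *pooling* events across recordings meaningful.
3. **Centered moving average.** A 9-sample centred window — about
   `r round(9/8.7, 2)` s at 8.7 samples/s — suppresses residual ripple.
   Offline processing is assumed, so the window can be centred (no lag). At
   the edges the window is *truncated*, never padded or reflected: output
   length equals input length and no synthetic extrema are created.
4. **Breath minima.** Breath events are strict local minima of the smoothed
   signal (the inhalation/exhalation turning point). Two constraints reject
   spurious candidates: a minimum separation of 0.6 s (just below the 1-s
   period of the fastest physiological breath; when two candidates collide
   the deeper wins, ties to the earlier) and a minimum prominence of 0.2 z
   (above the smoothed noise floor at the default noise level). Both are
   exposed in the configuration because neither is a measured quantity.

The value of the smoothed signal at each minimum is the event's **depth**
(z-units, more negative = deeper).

**Missing samples** (frames where segmentation found no nostril) are linearly
interpolated when the gap is at most 1 s; longer gaps split the recording
into segments that are filtered and standardized independently, because
interpolating across a long dropout would fabricate breaths. Segments shorter
than three low-edge cycles (131 samples at the defaults) are dropped with a
warning.

```{r chain}
rec <- simulate_recording(sim_config(duration_s = 120, seed = 42))
res <- analyze_series(rec$series)
head(res$events, 3)
```

## Labeling and classification

Each annotated regurgitation at time $t$ opens a half-open window
$[t, t + 3\,\mathrm{s})$; every breath event inside the union of windows is
labeled PRDI, everything else NRI. Half-open bounds avoid double counting at
exact boundaries; window membership is order-independent. All minima inside a
window are PRDI — the simulator's "true deep trough" is a stricter notion
used only for synthetic diagnostics.

Classification is a single threshold on depth: predict PRDI iff
$\mathrm{depth} \le \tau$. Equality counts as positive, matching the ROC
convention used in evaluation, and raising $\tau$ can only grow the
predicted-positive set (so sensitivity is non-decreasing and specificity
non-increasing in $\tau$ — asserted as a property test).

## Evaluation statistics

With PRDI as the positive class, the confusion counts give

$$\mathrm{Sensitivity} = \frac{TP}{TP+FN}, \qquad
  \mathrm{Specificity} = \frac{TN}{TN+FP},$$
$$\mathrm{G\text{-}mean} = \sqrt{\mathrm{Sens} \times \mathrm{Spec}}, \qquad
  \mathrm{Balanced\ accuracy} = \frac{\mathrm{Sens} + \mathrm{Spec}}{2}.$$

NRI far outnumbers PRDI, so plain accuracy would be dominated by the negative
class; both summary metrics weight the classes equally, and by the AM–GM
inequality G-mean never exceeds balanced accuracy, with equality exactly when
sensitivity equals specificity (another property test).

* **Mann–Whitney U.** Depth distributions of the two classes are compared
  with a two-sided Mann–Whitney test, oriented so that
  $U = \#\{(a,b): a<b\} + \tfrac12\#\text{ties}$ is large when PRDI minima
  are deeper. For $n_a n_b \le 400$ the p-value is exact even under ties,
  computed from the permutation distribution of the rank sum by a shift
  (dynamic-programming) algorithm over doubled midranks; larger problems use
  the normal approximation with tie and continuity corrections. The exact
  variant is implemented in-package because the standard exact routines
  decline tied data; it is cross-checked against `wilcox.test` on tie-free
  instances.
* **ROC / AUC.** Score $= -\mathrm{depth}$. The curve is traced over the
  candidate-threshold grid and the AUC is the trapezoidal area, which equals
  the tie-aware concordant-pair fraction $U/(n_{\mathrm{pos}}
  n_{\mathrm{neg}})$ — an identity asserted to $10^{-12}$ over hundreds of
  random instances.
* **Threshold sweep and selection.** Candidate thresholds are the midpoints
  between consecutive sorted unique depths, plus one candidate below the
  minimum and one above the maximum. Midpoints (rather than observed depths)
  make tie behaviour at the boundary unambiguous while still visiting every
  achievable confusion table. The *plateau* is the longest contiguous run of
  candidates attaining the maximum of both G-mean and balanced accuracy
  simultaneously (first run on ties), and the selected threshold is the
  plateau's arithmetic midpoint, which is robust to small signal
  fluctuations. The two argmax sets can fail to intersect on imbalanced
  data; the fallback is then the balanced-accuracy plateau, the choice is
  recorded in the fit and announced with a message. This deterministic rule
  is needed because "maximize both simultaneously" is not always attainable.

```{r fit}
ev <- label_events(res$events, build_windows(rec$regurg_times_s))
fit <- prdi_fit(ev)
fit
```

`coef()` returns the threshold, `predict()` classifies new depths, and
`plot()` draws the ROC curve with the two metric-versus-threshold curves.

## The simulator

`simulate_recording()` generates `baseline + drift + breathing + noise` with
ground truth, under defaults chosen to mirror the intended recording
conditions:

| parameter | default | rationale |
|---|---|---|
| `fs` | 8.7 samples/s | acquisition frame rate |
| `duration_s` | 120 s in studies | recordings are 1–2 min sessions |
| `breath_rate_hz` | 0.5 Hz | centre of the 0.2–1.0 Hz physiological band |
| `breath_amp_C` | 0.5 °C | realistic nostril oscillation amplitude |
| `baseline_C` | 30 °C | nostril surface temperature |
| `regurg_interval_mean_s` / `sd` | 37.5 / 9.73 s | observed calf rumination intervals |
| `regurg_interval_min_s` | 10 s | hard floor of the truncated-normal renewal process |
| `apnea_s` | 1.0 s | respiratory pause per regurgitation; not a measured value for calves, a modeling choice |
| `prdi_depth_factor` | 2.0 | amplitude multiplier of the compensatory deep inspiration |
| `noise_sd_C` | 0.1 °C | sensor noise |
| `drift_amp_C` | 0.2 °C | slow ambient/handheld drift (0.01-Hz sinusoid + random walk); mostly removed by the 0.2-Hz high-pass edge |
| `harmonic2_frac`, `amp_jitter_sd` | 0.2, 0.1 | second harmonic and per-breath log-normal amplitude jitter, so the waveform is quasi-periodic and the chain cannot rely on exact sinusoidality |

Breathing is laid down breath by breath; amplitudes change only at waveform
zero crossings, so the signal stays continuous. Regurgitations are scheduled
by the truncated-normal renewal process and **fire at the next breath-cycle
boundary**, where the waveform is exactly zero. This construction has three
consequences worth stating plainly:

* the apnea hold (flat oscillation, baseline retained) is continuous by
  construction, with no ramp artefacts for the filter to ring on;
* after the apnea the waveform resumes at the inspiration onset (phase
  $\pi$), so the deepened trough lands a fixed, analytically known offset
  after the event — always inside the 3-s window (the configuration is
  validated for this, and it is asserted exactly in the tests);
* in the null configuration (`prdi_depth_factor = 1`, `apnea_s = 0`) the
  waveform is *bit-identical* to an event-free recording — events are pure
  bookkeeping — so the check that post-regurgitation troughs are
  statistically indistinguishable from ordinary troughs is a true null.

Snapping events to cycle boundaries perturbs individual event times by up to
one breath period but leaves the interval distribution's mean unchanged
(the shifts telescope); the simulated inter-regurgitation intervals still
average 37.5 s, which is verified over 200 seeded replicates.

`render_frames()` optionally expands a recording into thermal frames plus
binary nostril-ellipse masks at a higher (RGB-like) resolution, with optional
pixel noise and per-frame mask jitter. The thermal footprint is the
block-downscaled mask, so noiseless rendering round-trips through
`series_from_frames()` to the input series within $10^{-6}$ °C.

**What the simulator does not model:** remastication jaw rhythm, head motion,
acoustic signatures, radiometric camera physics (emissivity, distance
effects), or realistic segmentation failure modes (masks drop out at random,
they do not drift onto the muzzle). Its breathing is narrow-band and its
events are cleaner than field data. Passing tests therefore demonstrate that
the *pipeline* is correct — filters do what their magnitude response says,
events land where constructed, statistics equal their definitions and
oracles — not that field recordings of real calves would reach the same
performance. On synthetic data at the defaults the pooled AUC is above 0.95
and the class medians sit around $-1.1$ vs $-0.85$ z; field data are messier
(reported AUCs are nearer 0.76 and the depth separation wider but noisier).

## Numerical choices and degenerate inputs

* Sample (n−1) standard deviation in the z-score; affine invariance is
  tested.
* Strict local minima only: plateaus of exactly equal samples do not produce
  events (they do not occur for continuous-valued signals).
* Prominence is computed scipy-style on the inverted signal: walk out from
  the minimum to the first strictly lower sample or the edge, take the
  highest point on each side, and use the lower of the two sides.
* Zero-variance (constant) segments, single-class event sets, and empty
  groups raise typed validation errors rather than producing NaN metrics;
  an all-false mask yields a missing sample, not an error.
* Threshold candidates at $\pm\infty$ behave as "predict everything /
  nothing"; sentinels one unit beyond the extreme depths are part of every
  sweep so the ROC always starts at (0,0) and ends at (1,1).
* Outputs embed a 32-bit FNV-1a hash of the analysis configuration so runs
  can be matched to their parameters; identical configuration and inputs
  reproduce byte-identical outputs.

## Problem sizes

The bundled studies use 30 recordings of 120 s for threshold-recovery
checks, 50 seeds of 300 s for the null-configuration check, and 200 seeds of
600 s for the interval statistics — sizes at which every reported behaviour
is stable across seeds while the whole suite stays quick to run.

## Known limitations

* Masks are aligned to the thermal grid by uniform block scaling only; no
  parallax or field-of-view registration is attempted.
* The apnea duration in calves is a modeling default (1.0 s), not a measured
  value.
* The classifier is a single global depth threshold on pooled standardized
  events; per-animal or per-recording thresholds, confidence intervals on
  AUC, and cross-validation are out of scope.
* No real-time operation: the centred smoother and zero-phase filter are
  offline constructs by design.
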