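---
title: "Noninvasive ICP pulse-waveform morphology: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive ICP pulse-waveform morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpwave)
```

## The problem

Each heartbeat drives a pressure pulse through the intracranial compartment.
On the intracranial pressure waveform (ICPW) this pulse carries three
sub-peaks: P1, the arterial percussion wave; P2, the cerebral blood-volume
(tidal) component; and P3, following aortic valve closure. In a compliant
skull P1 dominates. As the volume-pressure reserve (intracranial compliance)
is spent, P2 rises relative to P1 and the dominant peak of the averaged
pulse arrives later in the cardiac cycle. Two scalar summaries capture this:
the **P2/P1 amplitude ratio** and the **normalized time-to-peak (TTP)**.

The same morphology is visible from outside the skull: cardiac-driven
cranial micro-deformations (micrometre scale) reproduce the ICPW shape, so a
skin-coupled strain sensor can monitor compliance surrogates without a
catheter. Absolute pressure is not available from such a sensor — only the
waveform — which is why everything this package computes from the
displacement channel is deliberately **gain-invariant**: multiplying a
channel by any positive constant changes no ratio and no latency. That
single property is what makes a µm-scaled channel comparable with a
mmHg-scaled one.

`icpwave` implements the full chain: beat segmentation synchronized to
arterial blood pressure (ABP), artifact screening, per-minute ensemble
averaging, P1/P2 landmark extraction, and a validation layer (Bland-Altman,
bootstrapped Pearson correlation, ROC against intracranial hypertension)
exercised on a synthetic paired-signal generator with known ground truth.

## The pulse model

One cardiac cycle is modelled as the sum of three positive Gaussian bumps on
the cycle-phase axis $p \in [0, 1)$:

$$f(p) = \sum_{i=1}^{3} a_i \exp\!\left(-\tfrac{1}{2}\Big(\frac{p - t_i}{w_i}\Big)^{2}\right),$$

with the chord between $f(0)$ and $f(1)$ subtracted so the pulse begins and
ends at zero. Defaults: latencies $t = (0.15, 0.40, 0.65)$, widths
$w = (0.08, 0.10, 0.09)$, P3 at 45% of P1. Gaussian bumps were chosen over
raised cosines because their overlap produces the merged P1-P2 shoulder seen
in decompensated waveforms naturally as $a_2/a_1$ grows, rather than by a
separate mechanism.

Because the bumps overlap, the *apparent* peak heights of $f$ differ from
the generative amplitudes: at the default geometry, a generative
$a_2/a_1 = 1.2$ yields an apparent ratio near 1.22. Ground truth is
therefore defined as the **apparent morphology of the analytic pulse on a
dense phase grid** (`apparent_morphology()`), not as $a_2/a_1$; that is the
quantity an ideal estimator could recover from the rendered signal.

## The synthetic session

`generate_session()` emulates a 10-minute paired monitoring session
(defaults; all values configurable):

* sampling rate 200 Hz; constant heart rate 70 bpm, so a 600-s session holds
  exactly $\lfloor 600 \cdot 70/60 \rfloor = 700$ beats;
* invasive ICP channel in mmHg: configured mean ICP (the pulse train is
  centred to its cycle mean, so `baseline_icp_mmHg` is the monitor-style
  mean including pulsatility), P1 pulse component 4 mmHg, white noise
  SD 0.5 mmHg;
* respiratory modulation at 15/min: an additive baseline wave
  (0.5 mmHg) plus a ±10% per-beat amplitude modulation. The amplitude
  factor is frozen at each beat onset so a beat's morphology ratio is
  exactly its ground-truth value; a per-sample modulation would tilt single
  beats by a few percent and only average out;
* noninvasive displacement channel in µm: the identical per-beat morphology
  through an arbitrary gain (default 1 µm/mmHg of pulsatile component; the
  physical gain of a strain sensor is unknown and irrelevant to
  morphology), plus slow sinusoidal drift (2 µm, 100-s period) and white
  noise (0.3 µm);
* ABP channel: a gamma-like beat $(p/0.26)^{1.3} e^{-(p-0.26)/0.2}$ scaled
  to 80 + 40 mmHg, with a small dicrotic bump. It rises from exactly zero
  at the beat onset and decays monotonically through diastole, so the
  end-diastolic trough — the beat anchor — is sharply identifiable;
* jugular-compression plateau: from minute 7, for 60 s, the ICP baseline
  rises by the configured delta (raised-cosine 2-s edges) and the
  generative $a_2/a_1$ shifts by `compression_delta_p2p1`;
* artifacts at 2/min: motion spikes (8× the median beat amplitude, 24-ms
  Gaussian transient) and flat dropouts, injected into the ICP and
  displacement channels only — the arterial line is a separate transducer —
  with the corrupted beat indices recorded in the ground truth.

Sessions are pure functions of their config: a single integer seed drives
all randomness, and cohort seeds spawn per-session seeds deterministically.

What the generator does **not** emulate: heart-rate variability and ectopy,
nonstationary vasogenic waves, sensor coupling changes mid-session,
ABP-channel artifacts, and any nonlinear mapping between intracranial
pressure and cranial strain. Tests passing on this generator therefore
demonstrate correctness of the *analysis*, under a signal model whose
assumptions (ABP-anchored beats, shared morphology across channels,
stationary baseline epochs) real data may violate.

## Cohort generation and the compliance coupling

`generate_cohort()` draws per-session parameters from a group table
(`group_parameters()`) with three cranial-status groups — intact skull,
craniotomy/large fracture, craniectomy — mixed 12/20/9 per 41 sessions.
Baseline mean ICP is drawn at 15.2/15.6/20.8 mmHg (SD 7.1/7.4/9.4);
compression raises ICP by 4.1/4.1/3.13 mmHg and shifts the generative ratio
by +0.08/+0.07/−0.04. The craniectomy sign is negative: with the bone flap
out, volume loading vents through the defect instead of stiffening the
compartment.

The between-session response SD for the ratio delta defaults to 0.05.
Published per-patient spreads for such deltas are several times larger, but
they fold in pulse-level measurement noise and clinical heterogeneity that
the simulator represents explicitly elsewhere (sensor noise, artifacts,
respiratory modulation); the generator's delta SD is the spread of the
*true* underlying response, kept small enough that a 41-session cohort
expresses the group means it was parameterized with.

Baseline P2/P1 is drawn with a **compliance coupling** to baseline ICP
(0.02 ratio units per mmHg around the group mean, residual SD 0.15):
higher-pressure patients sit lower on the pressure-volume curve and show
proportionally larger P2. This cross-session coupling — not the 60-s
compression — is what gives the minute-level ratio its power to classify
intracranial hypertension in cohort ROC runs. `null_effect_parameters()`
zeroes every morphology-pressure link (compression deltas, the coupling,
and the group-level ratio offsets) while leaving the pressure model intact;
it is the appropriate null when checking that the ROC machinery finds no
signal where none exists. Zeroing only the compression delta would leave
the coupling in place and the AUC well above chance — that would be a test
of a different null.

## The estimator

1. **Beat detection** (`detect_beats()`): the ABP channel is lightly
   smoothed (~20-ms moving average); one systolic peak is taken per
   contiguous run above the amplitude mid-range, low secondary peaks are
   screened against the median peak height, a 0.25-s refractory period is
   enforced, and each onset is the last raw-signal minimum before its peak
   — the diastolic trough preceding the upstroke. The same onsets segment
   all channels; this ABP anchoring is what lets the noisy displacement
   channel borrow beat timing it could not supply itself.
2. **Segmentation** (`segment_pulses()`): onset-to-onset cuts, each re-based
   to start at zero (removing drift and respiratory baseline). A trailing
   span covering 95-105% of the median beat length is kept as a final beat;
   shorter tails are dropped.
3. **Artifact screening** (`exclude_artifacts()`): a beat is flagged when
   its peak-to-trough amplitude or duration leaves a median ± 3 robust-SD
   band (MAD-scaled with a 5%-of-median floor, since a clean constant-rate
   session has near-zero MAD and an unfloored band would flag everything),
   or when its correlation with the session's per-sample median pulse
   (all beats resampled to 100 samples) falls below 0.6 — flat dropouts
   land here with undefined correlation. Flags only; nothing is deleted.
   The median template is global to the session rather than running:
   sessions are 10 minutes and stationary by construction, and a windowed
   template adds estimation noise without bias benefit at this length.
4. **Minute averaging** (`minute_average()`): beats are assigned to minutes
   by onset, useful beats resampled to 100 samples/cycle (positions on the
   averaged pulse are thereby cycle fractions, decoupled from heart rate)
   and averaged pointwise with per-sample SDs. Minutes with fewer than 10
   useful beats carry a low-support flag.
5. **Landmarks** (`locate_peaks()`): P1 is the highest local maximum with
   position in [0.05, 0.30) of the cycle, P2 the highest in [0.25, 0.60) to
   the right of P1, amplitudes measured above the pulse-onset value. When a
   window holds no local maximum — the merged-shoulder regime — the
   landmark is placed at the zero crossing of the second derivative of a
   Savitzky-Golay smoothed copy (cubic, 11-sample window) inside the
   window, choosing the crossing nearest the other landmark (nearest the
   window centre if both are missing), and `merged_peaks` is set. If
   neither window resolves, the minute is reported as an explicit gap, not
   dropped. TTP is the position of the global maximum.

The windows are a design choice, not a published constant: the clinical
device's landmark algorithm is proprietary, and the windows here simply
bracket the default latencies with room for disease-driven drift; they are
exposed in `analysis_params()`. TTP is defined as a *fraction of the cycle*
rather than in seconds — the dimensionless thresholds quoted for such
monitors (e.g. 0.2, with observed ranges 0.05-0.45) are only consistent
with a normalized measure, and normalization removes heart-rate
confounding. Both interpretations are stated here prominently because they
are interpretations.

## The validation layer

* `bland_altman()`: differences oriented invasive − noninvasive; limits of
  agreement are bias ± 1.96 sample SDs (n − 1); the outlier fraction counts
  differences strictly outside the limits.
* `pearson_bootstrap()`: product-moment r with a 95% percentile bootstrap
  CI (2000 resamples, seeded). Percentile rather than BCa: at the n of
  minute-level cohorts the difference is immaterial and percentile is the
  simplest defensible default.
* `roc_curve()`: thresholds at all distinct scores, positive call at
  score ≥ threshold, AUC by trapezoid — provably equal to the Mann-Whitney
  pair-count probability with half credit for ties, which
  `auc_mann_whitney()` computes independently and
  `auc_equivalence_check()` verifies to 1e-12. The Youden-optimal cut-off
  is reported; a seeded bootstrap AUC CI (`roc_auc_ci()`) is provided as an
  extension.
* Unit of analysis: minute-level metrics pooled across sessions, labels
  from the invasive channel's same-minute mean (> 20 mmHg). Minutes within
  a session are correlated — a session's baseline minutes share one
  morphology and one label — so pooled AUCs and correlations have far
  fewer effective degrees of freedom than rows; cohort-level results on
  synthetic data are structural checks, not precision estimates.

## Numerical choices and degenerate inputs

* Resampled beat length 100; landmark positions are quantized to 0.01 of
  the cycle, so position assertions carry ±1-sample tolerances.
* A flat channel (range below 1e-10 of scale) raises "no beats detected";
  a flat averaged pulse raises "morphology undetermined"; a nonpositive P1
  amplitude is refused rather than returning a negative ratio.
* All screening thresholds are relative (medians, MADs, quantiles,
  correlations); no absolute constant anywhere in the morphology path, which
  is what makes the 1e-12 gain-invariance check attainable.
* Tie-breaks: equal-height local maxima resolve to the first (earliest);
  equal troughs to the last (closest to the upstroke).

## Problem sizes used in the test suite

The suite validates at the study's natural scale where that is cheap (one
600-s session; a 41-session cohort for the group-direction and ROC checks)
and at reduced scale where many replicates are needed: morphology-recovery
sweeps use 120-s sessions (two minutes is already 140 beats per estimate),
and the null-ROC calibration uses ten cohorts of 24 × 240-s sessions —
shorter sessions buy more independent sessions per unit compute, which is
what the clustered AUC's variance actually depends on. The null band is
checked on the mean AUC over the ten seeded cohorts: a single cohort of
this size has an AUC sampling SD near 0.1 under the null (about 24
effective units), so a per-seed band would mostly measure that sampling
noise.

## Known limitations

* Constant heart rate: no HRV, so duration-based artifact screening is
  stricter on synthetic data than it would be on real beats.
* The landmark windows assume roughly physiological latencies; gross
  bradycardia-driven shape changes or inverted P1/P2 orderings outside the
  windows surface as merged/undetermined minutes rather than relocated
  landmarks.
* The agreement layer treats minutes as exchangeable within the pooled
  analysis; no mixed-effects correction for within-session correlation is
  attempted (the per-group splits are the provided mitigation).
* Compression epochs come from configuration, never from plateau
  detection; analysing real recordings requires the compression timing as
  metadata.
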