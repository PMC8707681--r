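# icpwave

Morphology analysis of intracranial pressure (ICP) pulse waveforms, for
neurocritical-care monitoring research: invasive (mmHg) and noninvasive
(cranial micro-displacement, µm) recordings analysed with one shared,
gain-invariant pipeline.

## The problem and the statistic

Every heartbeat produces an intracranial pressure pulse with three
sub-peaks: P1 (arterial percussion), P2 (cerebral blood-volume component)
and P3 (after aortic valve closure). When intracranial compliance falls, P2
grows relative to P1 and the dominant peak of the averaged pulse arrives
later. Two dimensionless summaries track this:

* **P2/P1 ratio** — the amplitude ratio of the two landmarks on the
  per-minute ensemble-averaged pulse, amplitudes measured above the pulse
  onset;
* **TTP** — the position of the global maximum of the averaged pulse as a
  fraction of the cardiac cycle.

Being ratios and normalized latencies, both are invariant to channel gain,
which is what makes a µm-scaled skin sensor comparable with a mmHg-scaled
catheter. The pipeline is: beat onsets detected on the arterial blood
pressure channel (diastolic trough before the systolic upstroke, 0.25-s
refractory) → onset-to-onset segmentation of the ICP and displacement
channels → robust artifact flagging (amplitude/duration median ± 3 MAD
bands, template correlation ≥ 0.6) → per-minute averaging of useful beats
resampled to 100 samples/cycle → P1/P2 localization in the [0.05, 0.30)
and [0.25, 0.60) cycle windows, with a smoothed-second-derivative
inflection fallback for merged shoulders.

The package also ships the validation layer used to compare modalities —
Bland–Altman limits of agreement (bias ± 1.96 SD), Pearson correlation with
percentile-bootstrap CIs, ROC/AUC of the noninvasive ratio against
intracranial hypertension (invasive minute mean > 20 mmHg) — and a
synthetic paired-signal generator that emulates 10-minute sessions with a
60-s internal-jugular-compression plateau at minute 7, three cranial-status
groups (intact skull, craniotomy/fracture, craniectomy), respiratory
modulation, sensor noise, drift and injected artifacts, with per-beat
ground-truth morphology.

## Worked example

```r
library(icpwave)

cfg <- session_config(group = "intact", seed = 1)   # 600 s, 70 bpm, 200 Hz
ses <- generate_session(cfg)                        # paired recording + truth
rep <- analyze_session(ses$recording)
print(rep)
```

```
ICP waveform session report
  beats detected: 700; minutes analysed: 10
  mean ICP: 15.2 mmHg baseline, 19.2 mmHg during compression
  icp: P2/P1 1.015 -> 1.100 (delta +0.085); TTP 0.326 -> 0.380
  b4c: P2/P1 1.010 -> 1.099 (delta +0.089); TTP 0.367 -> 0.400
```

Reading: the 10-minute session holds exactly 700 beats at 70 bpm, all
recovered from the ABP channel. Jugular compression raises mean ICP from
15.2 to 19.2 mmHg, and both the invasive (`icp`) and noninvasive (`b4c`)
channels report the accompanying compliance change the same way: the P2/P1
ratio climbs by ≈ +0.09 and the averaged pulse peaks later in the cycle.
`rep$per_minute` holds the minute-by-minute table behind the summary;
`plot(rep)` draws the monitoring panels (ratio, TTP, pulse amplitude,
useful-pulse counts).

Agreement between the two channels' minute series:

```r
pm <- rep$per_minute
bland_altman(pm$p2p1_ratio[pm$channel == "icp"],
             pm$p2p1_ratio[pm$channel == "b4c"])
```

```
Bland-Altman agreement (differences: invasive - noninvasive)
  n = 10, bias = 0.00385, SD(diff) = 0.01931
  95% limits of agreement: [-0.03399, 0.04169]  (bias +/- 1.96 SD)
  outliers beyond limits: 10.0%
```

Cohort-scale validation (41 sessions, group mix 12/20/9, agreement +
correlation + ROC per group and pooled, and the group-wise compression
delta table):

```r
cohort <- generate_cohort(41, seed = 1)
validate_cohort(cohort)
```

A thin CLI over the same functions lives in `inst/cli/icpwave.R`
(`simulate`, `analyze`, `validate` subcommands).

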