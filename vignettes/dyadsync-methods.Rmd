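---
title: "Methods: dyadic fNIRS synchrony with normalized DTW distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic fNIRS synchrony with normalized DTW distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The scientific question and the measurement chain

dyadsync quantifies *interpersonal neural synchrony* — the temporal alignment
of two people's brain activity — from dyadic fNIRS hyperscanning recordings
made while romantic partners co-view emotive videos, and relates it to how
far apart the partners' relationship satisfaction is.

The full chain the package implements:

1. **Paradigm**: seven cycles of a 60 s fixation cross followed by a 114 s
   video (three positive stimuli — happiness, love, pride; three negative —
   sadness, fear, disgust; one neutral), 1218 s in total, in one of three
   counterbalanced orders (`make_schedule()`).
2. **Questionnaire**: the 7-item Relationship Assessment Scale, 7-point
   Likert, items 4 and 7 reverse-keyed, scored as the item mean
   (`score_ras()`); the dyadic predictor is the absolute score difference
   (`satisfaction_difference()`).
3. **Preprocessing** (`preprocess_dyad()`), in fixed order per subject:
   channel quality screen (exclude if gain > 8 or CV > 7.5), despiking,
   zero-phase 0.01–0.2 Hz band-pass, modified Beer–Lambert conversion of the
   760/850 nm optical densities to ΔHbO/ΔHbR (µM).
4. **Synchrony** (`compute_dyad_synchrony()`): per channel and per video
   block, Dynamic Time Warping between the partners' ΔHbO segments under the
   symmetric2 step pattern; the *normalized distance index* is the total
   alignment cost divided by N + M, the combined length of the two segments.
   Larger distance = lower synchrony.
5. **Aggregation** (`aggregate_roi_condition()`): channels → ROI (frontal
   left {4, 6, 7, 11}; frontal right {13, 14, 16, 19}, covering VLPFC, VMPFC
   and OFC), then blocks → condition (positive / negative / baseline), both
   unweighted means.
6. **Statistics** (`synchrony_stats()`): Kruskal–Wallis across the three
   conditions (and the two-group emotion-vs-baseline variant, the same
   operation with two groups); per-ROI OLS of the index on the satisfaction
   difference and a positive-emotion dummy; Pearson correlation between the
   satisfaction difference and the emotion-averaged right-cluster index.

## The DTW core

The alignment is a from-scratch dynamic program (C++ inner loop):

$$D_{1,1} = c_{1,1}, \qquad
D_{i,j} = \min\big(D_{i-1,j-1} + 2c_{i,j},\; D_{i-1,j} + c_{i,j},\;
D_{i,j-1} + c_{i,j}\big)$$

with local cost $c_{i,j} = |x_i - y_j|$ (the symmetric2 pattern, whose
standard normalization constant is $N + M$ — exactly the divisor of the
normalized distance index). Backtracking prefers the diagonal step on ties,
so reported paths are deterministic. An optional Sakoe–Chiba band
(`window`) bounds $|i - j|$; it is off by default — a full 890 × 890 grid
per block is desk-scale — and the unconstrained optimum is reproduced
whenever the band is wide enough. The implementation is validated in the
test suite against exhaustive enumeration of all monotone warping paths for
short series, an oracle that shares no code with the dynamic program.

Design choices: absolute (not squared) local cost, matching the default of
the R DTW tooling this index convention comes from; no per-segment
z-normalization by default (the index then stays in concentration units);
ΔHbO as the default input signal (configurable to ΔHbR or the HbO/−HbR
average).

## The synthetic cohort: what it emulates

`simulate_cohort()` is a forward model of the study conditions, not a
convenience fixture. Per channel, each partner's true ΔHbO is

$$\kappa\,s(t) + (1-\kappa)\,u(t) + \varepsilon(t)$$

where $s$ is the dyad-shared condition-locked response, $u$ the subject's
idiosyncratic response, $\kappa \in [0,1]$ the coupling strength, and
$\varepsilon$ physiological noise, always drawn independently per subject
(coupling acts on the stimulus-locked component only — the "shared
experience" construct). ΔHbR is $-\tfrac13$ ΔHbO plus independent noise,
the typical anticorrelation. Both chromophores are pushed through the
forward Beer–Lambert relation (extinction coefficients at 760/850 nm from
the standard haemoglobin compilation, 3 cm source–detector distance, DPF 6)
to per-wavelength optical densities, so preprocessing must genuinely invert
the optical map; the forward-then-inverse round trip is exact to numerical
precision in the noise-free case.

The condition-locked responses are HRF-convolved (canonical double-gamma:
peak 6 s, undershoot 16 s, ratio 1/6) stimulus drives: a per-block boxcar
with amplitude by valence (defaults 0.35 µM positive, 0.35 µM negative,
0.10 µM neutral), a per-block multiplicative gain (SD 0.3), and a
stimulus-locked *within-block* fluctuation (`modulation_sd`, default 1.0 ×
amplitude) representing the video's moment-to-moment content. That last
component is load-bearing: a 114 s block envelope has its fundamental near
0.006 Hz, *below* the 0.01 Hz high-pass edge, so almost none of a constant
block response survives the band-pass. What carries inter-brain coupling
into the analysis band is the within-block fluctuation, whose HRF-smoothed
power sits at ~0.01–0.1 Hz. The shared stream is drawn once per dyad (the
partners watch the same video), the idiosyncratic streams per subject.

Noise defaults (µM): cardiac 0.15 at 1.1 Hz, respiratory 0.10 at 0.25 Hz,
low-frequency waves 0.10 at 0.1 Hz (random phases per subject and channel),
white noise SD 0.05, linear drift with whole-recording excursion SD 0.10,
motion spikes at 0.002 /s of magnitude 1.5. These are typical magnitudes
for continuous-wave fNIRS relative to block responses of a few tenths of a
micromolar. Channel gain and CV metadata are drawn uniformly from ranges
that pass the quality screen by default (1–7 and 0.5–6); widen the ranges
to study attrition.

The coupling link is $\kappa = \mathrm{clip}(\beta_0 + \beta_1\,\Delta s +
\mathcal N(0, \sigma))$ with defaults $\beta_0 = 0.3$, $\beta_1 = 0.35$,
$\sigma = 0.1$: a dyad at the cohort-average satisfaction gap sits near
$\kappa \approx 0.5$, and the link direction reproduces the study's finding
(larger satisfaction gap → more shared response → *lower* distance index,
i.e. a negative regression slope). $\beta_1$ was sized from the package's
own dose–response behaviour — the derivative of the expected right-cluster
index with respect to $\kappa$ against the between-dyad spread of the index
— so that the true slope is detectable (sign recovered in ≥ 80% of
replicate cohorts) at the study's n = 15 dyads / 30 regression rows.
Satisfaction scores are drawn as $\mathcal N(4.4, 0.5)$ truncated to
$[1,7]$ per partner (matching the printed cohort descriptives, and giving a
mean absolute dyad difference near 0.58); item-level responses are the
latent score plus $\mathcal N(0, 0.5)$ noise, rounded, clamped, and
reverse-keyed where appropriate, then scored with the same `score_ras()`
the analysis uses.

What the generator does *not* emulate: photon transport and optode
geometry, scalp/systemic physiology layers, serially correlated (1/f)
noise, habituation across blocks, or emotion-specific response topography.
Green tests therefore certify the pipeline's arithmetic and its ability to
recover a known coupling structure under realistic noise — not that real
couples behave like the model.

## Numerical and procedural choices

* **Band-pass**: 3rd-order Butterworth applied forward–backward
  (`signal::filtfilt`), so the net filter has zero phase — essential, since
  phase shifts would masquerade as (a)synchrony. The series is demeaned
  before filtering: the forward–backward pass alone leaves a long transient
  at the 0.01 Hz edge for inputs with large DC offsets, while demeaning
  removes DC exactly. Contracts (verified in tests): DC to < 1e−8, ≥ 20 dB
  at 1.0 Hz, ≥ 90% RMS retention at 0.05 Hz, approximate idempotence on
  in-band content.
* **Despiking**: deviation from a centred 1 s moving median, flagged when it
  exceeds k = 5 times a robust scale, replaced by linear interpolation
  between the nearest clean neighbours (endpoints extended). The scale is
  the consistency-scaled moving median of absolute successive differences
  over a ≥ 31-sample window rather than the MAD of the
  deviation-from-own-median series: the latter has a point mass at zero
  wherever the signal is locally monotone (the centre of a short window is
  its own median there), which collapses the threshold and flags ordinary
  noise; successive differences have no such atom, while a lone spike still
  cannot inflate their median.
* **Quality screen**: strict inequalities (gain > 8, CV > 7.5 exclude), so
  the boundary values pass; applied per subject and wavelength-agnostic
  metadata; a channel enters the synchrony table only if retained in *both*
  partners, and every exclusion is logged once with a machine-readable
  reason.
* **Segmentation**: marker onsets in seconds map to samples by flooring;
  video windows are half-open `[floor(onset·fs), floor(onset·fs) +
  floor(114·fs))`, so blocks never overlap and, at 7.81 Hz, every video
  segment holds exactly 890 samples. Fixation intervals never enter DTW.
* **Aggregation order**: channels → ROI within block first, then blocks →
  condition (mean of means). The orders differ only under missing data; the
  choice is documented and the alternative reachable by aggregating a
  filtered synchrony table.
* **Kruskal–Wallis groups**: per-dyad right-cluster indexes per condition
  (the cluster is switchable). The three condition samples are repeated
  measures on the same dyads but are treated as independent groups —
  replicating the original analytic plan, not endorsing it; a
  repeated-measures test (e.g. Friedman) would be the statistically
  stricter choice.
* **Regression**: OLS of the index on the satisfaction difference and an
  emotion dummy coded positive = 1, baseline excluded; with a complete
  15-dyad cohort, 30 rows and residual df 27. The two rows per dyad come
  from the same recording session and share its noise realization (in
  particular the in-band low-frequency oscillation phase offsets between
  the partners, drawn once per session), so they are substantially
  correlated; plain OLS ignores that clustering and its standard errors are
  optimistic. This is a property of the replicated analysis itself, and the
  null-calibration experiment (zeroed link, 100 replicate cohorts) makes it
  visible: the slope's two-standard-error interval covers zero less often
  than the nominal ~95%. A dyad-level mixed model would be the stricter
  alternative; the package deliberately reports the replicated model.
* **Pearson correlation**: on per-dyad indexes averaged over the positive
  and negative conditions (n = 15, df = 13), which is the averaging that
  matches the printed degrees of freedom.
* **Determinism**: every stochastic step is seeded; per-dyad and
  per-replicate seeds derive from the master seed as
  `(master·48271 + i·16807) mod (2³¹ − 1)`, so cohorts are reproducible and
  stable under resizing, and `run_pipeline()` is byte-identical across runs
  of the same configuration.

## Problem sizes used by the replicated experiments

Single-cohort analyses (and all per-stage contracts) run at the study rate
of 7.81 Hz — 9512 samples per series, 890-sample DTW grids. The replicated
Monte-Carlo experiments (parameter recovery over 200 cohorts, null
calibration over 100 cohorts, each 15 dyads with full preprocessing and
DTW) use a 1 Hz simulation rate with a 3 s despike window — the package's
choice of problem size for experiments that repeat the entire pipeline
hundreds of times. The normalized DTW index (cost per aligned sample) and
the regression structure do not depend on the sampling rate; only absolute
index magnitudes do.

## Known limitations

* The CSV + JSON dialect is the only reader; SNIRF/HDF5 input is declared
  but not implemented in this build.
* No motion correction beyond despiking (no wavelet or spline correction),
  no short-channel or systemic-physiology regression.
* No pseudo-dyad permutation baseline: the faithful pipeline mirrors the
  original analysis, which did not use one. The synchrony table makes such
  an extension straightforward (pair subject *a* of one dyad with subject
  *b* of another).
* The statistical layer replicates the original plan, including its
  treatment of repeated measures; it is a replication surface, not a
  recommendation.
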