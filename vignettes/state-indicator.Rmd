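---
title: "Methods: the five-parameter EEG state indicator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the five-parameter EEG state indicator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`eegstate` implements a passive brain-computer-interface monitor: five
mental-state levels — attention, fatigue, stress, and left/right
hemispheric activity — computed once per second from multichannel EEG band
power. Every parameter is an affine transform of baseline-relative band
power onto a 0–10 scale centred at 5:

$$y(t) = 5 \pm \frac{1}{n}\sum_{c=1}^{n}\frac{P_c(t)-\bar P_c}{f_c},
\qquad f_c = \sigma_c/2,$$

where $P_c(t)$ is the band power of channel (or channel difference) $c$ in
the parameter's region of interest, $\bar P_c$ and $\sigma_c$ are the
across-subject mean and standard deviation of that feature in a
calibration cohort, and $n$ is the number of channels in the region. The
normalization factor is *half* the population standard deviation: if the
feature is Gaussian, a level leaves the 0–10 display range only when the
feature leaves $\mu \pm 2.5\sigma$, i.e. $2\Phi(2.5)-1 \approx 98.75\%$ of
levels fall inside the range. This robustness-to-outliers motivation is
the reason the scale is *not* clipped in data outputs — clipping happens
only in the pentagon display.

The five features are:

| parameter | sign | region | bands | form |
|---|---|---|---|---|
| attention | − | F3, Fz, F4 | theta, alpha | per-channel mean |
| fatigue | + | O1, Oz, O2 | theta, alpha, beta | per-channel mean |
| stress | − | F4 − F3 | alpha | ln-power difference |
| left activity | + | C4 − Cz | mu (8–13 Hz) | power difference |
| right activity | + | C3 − Cz | mu (8–13 Hz) | power difference |

Frontal theta/alpha is inverse to engagement, hence the minus sign on
attention; occipital broadband power rises with fatigue; frontal alpha
asymmetry $\ln P_{F4} - \ln P_{F3}$ indexes affect (positive scores mean
relatively stronger left-hemisphere activity and calmer states, so stress
carries a minus sign). Two conventions are kept exactly as the indicator
defines them even though a reader may find them surprising: the *left*
parameter reads C4 and the *right* parameter C3 (contralateral naming),
and mu power enters with a **+** sign although strict
event-related-desynchronization logic would associate higher mu with
*lower* activity. Both are documented at the feature definitions
(`feature_defs()`).

# The processing pipeline

1. **Bandpass 1–50 Hz.** Zero-phase forward–backward Butterworth. The
   design order defaults to 6: at 500 Hz the forward–backward order-4
   filter leaves 16% of a 60 Hz component, while order 6 leaves 8% and
   stays numerically stable (order 8 in transfer-function form is not).
   The passband (10 Hz) loses under 0.1%. A causal single-pass variant
   (`zero_phase = FALSE`) exists for strictly-streaming use; zero-phase is
   the default because it preserves event alignment.
2. **Artifact subspace reconstruction.** The 30-s pre-task baseline is the
   reference: its channel covariance is eigendecomposed, and per-component
   rejection thresholds are `median + cutoff_k * 1.4826 * MAD` of the
   windowed component RMS values (0.5-s windows, 50% overlap). Robust
   statistics tolerate small artifacts inside the baseline itself.
   `cutoff_k` defaults to 20, conservative within the 10–30 range of
   published practice. Processing projects each window onto the
   components, zeroes those whose RMS exceeds threshold, reconstructs from
   the retained subspace and blends windows by raised-cosine overlap-add;
   untouched windows pass through unchanged. Because the basis is
   orthonormal, cleaning can only shrink a window's total power. Windows
   live on a fixed global sample grid, so chunked (replayed) and
   whole-recording processing agree to numerical precision.
3. **Spectral decomposition.** One-sided Hann-tapered periodogram in
   µV²/Hz, expressed in dB (`10*log10`, floored at −120 dB so silence
   stays finite). Analysis windows are 2 s stepped by 1 s: 0.5 Hz
   resolution covering the 1–50 Hz range at the 1-s display refresh. The
   baseline PSD is the Welch-style mean over the 30-s baseline, averaged
   in the dB domain to match the dB-domain baseline subtraction (a
   `average = "linear"` switch exists). Band power is the mean of the dB
   bins whose centre lies inside the band, edges inclusive — so alpha
   (8–12) and mu (8–13) intentionally share bins.
4. **Norm calibration.** `fit_norms()` is the package's estimator: per
   feature it takes each subject's time-mean power, then the
   across-subject mean and sample standard deviation (n−1), and stores
   $f=\sigma/2$. Bands within a channel are averaged in dB *before*
   normalization, because each channel carries a single $(\bar P_c, f_c)$
   pair in the formulas. Stress is centred at zero asymmetry as the
   formula states (set `center_stress = TRUE` to centre at the cohort
   mean); the left/right differences are centred at their cohort means.
   For stress, linear alpha power is re-derived from the dB pipeline and
   natural-log transformed ($\ln P = \mathrm{dB}\cdot\ln 10/10$) — the
   asymmetry convention of the affect literature; a dB pipeline and an
   ln-power formula cannot both hold verbatim, and the ln-domain reading
   is the one kept.
5. **State computation.** `predict(norms, band_powers)` (or
   `compute_states()`) emits one five-parameter row per step;
   `render_pentagon()` draws a single time point.

# The paradigm and behavior scoring

The validation protocol is a 30-s baseline followed by four repetitions of
a 12-min target-detection session and a 5-min rest — a 68-min task. Each
session holds 180 trials, 60 per condition (congruent / incongruent /
no-target), shuffled within session by a seeded generator. The source
description is internally inconsistent ("five blocks" vs "repeated four
times" vs the 68-min total); the four-pair reading, which matches the
total, is the default, and `paradigm_spec(n_pairs = 5)` gives the other.
Per-trial timing is not specified there either; the package divides the
session evenly (4 s per trial: 0.5-s cue, then the target with a 2-s
response window), which reproduces the printed totals.

Scoring: a response matches the first following target; no-target trials
require the "up" key; reaction times above 2 s (or absent responses) fail
the trial. Summaries report per-condition median RT with linear (type-7)
interquartile bounds over responded non-timeout trials, and accuracy as
percent correct of all trials with timeouts counted incorrect.

# What the synthetic generator does and does not emulate

`synth_generate()` builds recordings from band-limited sinusoids with
per-component random phases, per-channel-independent 1/f noise, and
transient artifacts (0.3-s half-cosine blinks weighted onto frontal
channels; 20–45 Hz Gaussian-envelope EMG bursts weighted onto temporal
channels). Oscillation amplitudes follow piecewise-linear schedules, and
every oscillation waxes and wanes (slow random modulation, depth 0.4 by
default). The modulation matters: real alpha is strongly
amplitude-modulated, and a perfectly stationary baseline would give the
ASR calibration an unrealistically tight spread, causing it to reject
genuine high-amplitude physiology.

Cohorts draw each component's task amplitude Gaussian around
`task_gain` × base (baseline segments stay at base amplitude, so
baseline-subtracted powers vary across subjects). With
`between_subject_sd = 0` the cohort is literally one subject repeated and
`fit_norms()` raises its degenerate-cohort error. Named scenarios program
monotone per-period amplitude trends — rising frontal theta/alpha
(`attention_decay`), rising-then-relenting occipital broadband
(`fatigue_buildup`), growing F4−F3 alpha asymmetry
(`stress_habituation`), session-locked C3 mu elevation
(`mi_lateralization`) — and return the programmed trajectory for
comparison with the estimated one.

What it does **not** emulate: volume conduction and source mixing across
channels, biophysical head models, non-sinusoidal waveform shape,
heavy-tailed artifact statistics, electrode drift and impedance changes.
Passing end-to-end tests therefore demonstrate that the pipeline recovers
programmed band-power trends through filtering, artifact rejection and
normalization — not that the five parameters measure the corresponding
psychological constructs in real subjects.

# Numerical choices and degenerate inputs

* dB floor −120 dB; zero windows stay finite.
* `compute_psd` requires ≥ 1 s of samples; shorter windows are a contract
  error rather than silently low-resolution spectra.
* Rank-deficient baseline covariance (duplicated or flat channels) aborts
  ASR calibration and names the offending channels.
* Cohort features with zero across-subject variance abort `fit_norms`.
* EDF quantizes to 16 bits of the per-channel physical range (BDF: 24);
  round trips are exact up to that quantization. Recordings are written
  as a single data record so arbitrary durations need no padding.
* Parseval checks in the test suite use 10–20 s windows: a Hann-tapered
  single periodogram estimates total power with ~9% RMS error at 1 s,
  which is a property of tapering, not a defect of the estimator.
* Problem sizes in the test suite are chosen for a laptop-class run:
  norms from an 8-subject cohort of 70-s recordings, trend-recovery
  scenarios with 3-min sessions and 1.5-min rests over nine channels at
  500 Hz, streaming-equivalence on a 3.5-min recording. The pipeline is
  linear in duration and channels; full-length 68-min scenarios run the
  same way.

# Known limitations

* The ASR variant reconstructs from the retained calibration subspace
  (component zeroing); it does not re-estimate a clean covariance per
  window as heavier offline implementations do.
* Norms depend on the calibration cohort's recording conditions; applying
  them to data from a different montage or reference is a contract error
  where detectable, and a silent bias where not.
* The mu-rhythm left/right parameters index power shifts only; they are
  explicitly not a motor-imagery classifier.
* Only EDF/BDF/CSV recordings and TSV event tables are read; vendor
  formats are out of scope.
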