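---
title: "Methods: pre/during/post electrophysiology of music-assisted relaxation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre/during/post electrophysiology of music-assisted relaxation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`marphysio` reimplements, as a tested pipeline, a within-subject analysis of
multimodal electrophysiology recorded around music-assisted relaxation (MAR)
sessions with burn patients in intensive care. Every session is divided into
three annotated periods — baseline rest (PRE), the music-therapy
intervention (MTI), and post-intervention reincorporation (POST) — and each
modality is reduced to period-level features that are compared across the 17
recordings of the cohort with permutation tests. This vignette documents the
model, the fixed numerical dialects, the synthetic-data generator used to
validate every stage, and the choices made where the design was genuinely
open.

## Session model and windows

A session holds up to three `recording` objects (EEG: the 8-electrode 10-20
subset Fp1, Fp2, T3, T4, C3, C4, O1, O2 referenced to Cz; one bipolar ECG
lead; one bipolar facial-EMG pair over the corrugator supercilii) and one
`period_segmentation` built from explicit PRE/MTI/POST annotations — periods
are never inferred from the signal. Time is in seconds with half-open
intervals `[start, end)`; sample indices are 0-based with
`end index = floor(end * fs)`, so epoch counts are unambiguous.

Analysis uses the central window of each period with targets of 5, 15 and
5 minutes (PRE, MTI, POST). A period shorter than its target is used whole;
this rule is applied to all three periods, including MTI, since session
durations in the ICU vary widely. Non-integer trims put the extra time on
the right edge, which makes windowing deterministic.

## Spectral dialect

All power spectra are Welch estimates: overlapping segments, a minimum
4-term Blackman-Harris window, per-segment mean removal, density scaling
(`|FFT|^2 / (fs * sum(w^2))`, one-sided), arithmetic averaging. Band power
is the composite Simpson integral of the density over the grid points inside
the band. Two deliberate numerical choices interact here:

* **Segment lengths put every band edge on the frequency grid at an even
  pair offset.** EEG epochs (3 s, 1.5-s overlap) use 2-s segments with 50%
  overlap (0.5-Hz grid; resolution requirement is ≤ 1 Hz); EMG epochs (2 s,
  1-s overlap) use 1-s segments (1-Hz grid); the 4-Hz tachogram uses
  `min(T, 200 s)` segments (0.005-Hz grid). With the default bands
  (Delta 1–4, Theta 4–8, Alpha 8–12, SlowBeta 12–18, FastBeta 18–30 Hz; LF
  0.04–0.15, HF 0.15–0.4 Hz; EMG 20–200 Hz) this alignment makes Simpson
  band integrals *exactly* additive over a contiguous partition — the five
  EEG band powers sum to the 1–30 Hz integral to machine precision, and
  LF + HF + the out-of-band remainder is exactly the total tachogram power.
* **The Blackman-Harris window (not Hann) keeps Simpson quadrature honest on
  narrowband signals.** Simpson weights alternate 4/3 and 2/3 across grid
  points, so a spectral line concentrated on ~3 bins (the Hann line shape)
  is systematically mis-integrated by up to ±11% depending on which parity
  the peak lands on. The Blackman-Harris line spreads smoothly over ~7 bins
  and integrates to within ~3%; a unit 10-Hz sinusoid recovers its power of
  0.5 within a few percent.

The EMG mean frequency (MNF) is the spectral centroid of the
mean-then-normalized period PSD over 20–200 Hz, computed by the discrete
weighted-mean formula and cross-checked internally against the ratio of
Simpson integrals of `f·P(f)` and `P(f)` (0.1 Hz tolerance on period-mean
spectra; per-epoch spectra fluctuate more, so the optional
mean-of-per-epoch-MNFs reading uses a 1-Hz cross-check). Both MNF readings
agree on stationary signals; the mean-then-normalize reading is the default.

## Preprocessing

Filters are 4th-order Butterworth designs applied forward-backward
(zero-phase by construction, effective 8th order) with reflect padding of
three filter time constants: 1–30 Hz for EEG, 1–40 Hz for ECG, 20–200 Hz
for EMG, plus a 60-Hz notch comb (2nd-order band-stop, ±1 Hz) with
harmonics up to 200 Hz for EMG. The 1-Hz high-pass edge has a slow
transient (~10 s to reach 10⁻⁶); windows used in analysis sit well inside
the padded region.

Ocular activity is removed with symmetric FastICA (tanh contrast,
deterministic under a fixed seed; the unmixing matrix is estimated on a
regular subsample of ≤ 32768 samples and applied to the full recording).
Components are scored by absolute correlation with a blink proxy — the mean
of Fp1 and Fp2 low-passed at 4 Hz — and at most the single top-scoring
component is zeroed. The removal threshold is 0.75: measured blink
components score above 0.9, while on blink-free data an ICA source aligned
with the Fp1+Fp2 direction of ordinary delta background can reach |r| ≈ 0.6,
so a 0.5 threshold would fire spuriously. When the data are rank-deficient
(e.g. re-decomposing after a removal) the decomposition works in the
numerically full-rank subspace.

Amplitude artifacts are flagged automatically (1-s windows whose peak
deviation from the channel median exceeds 5 channel-MADs), replacing the
original study's visual inspection for reproducibility; a user-supplied
annotations table can override the automatic mask. Epochs overlapping a
masked span — or a period boundary — are dropped, never truncated.

## Feature definitions

**EEG.** Per epoch, channel and band: Simpson band power, then
`z = (x − mean_PRE) / sd_PRE` per channel × band with the sample (n−1) SD,
so PRE epochs have mean 0 and SD 1 by construction. Period summaries are
arithmetic means of epoch z-scores; one number per recording per cell enters
the group statistics.

**ECG.** R peaks come from a derivative-energy detector (squared derivative
integrated over 120 ms, adaptive threshold at 0.4 × the running median of
recent accepted peak heights with an absolute floor so flatline segments
yield nothing, 250-ms refractory period, peak refinement to the trace
maximum within ±60 ms). R-R intervals outside 300–1500 ms are replaced by
linear interpolation between flanking valid values (the interval count never
changes; runs above 20% invalid abort with a quality error). Features per
period: meanRR, STDRR (sample SD), pRR50 (percentage of successive
differences strictly exceeding 50 ms); Poincaré SD1/SD2 on the R-R series
z-scored by the same session's PRE mean and SD — SD1 is the *uncentered*
population RMS of `(z_n − z_{n+1})/√2`, making SD1 ≡ RMSSD/√2 an exact
identity, SD2 the centered population SD of `(z_n + z_{n+1})/√2`; and the
LF/HF balance of the tachogram, cubic-spline resampled at 4 Hz (each R-R
value anchored at its terminating peak), mean-removed, Welch-transformed and
normalized by total 0–2 Hz power. For windows shorter than 300 s the lower
LF edge rises as `f_low = max(0.04, 12/T)` to keep at least 12 cycles in the
window; below T = 80 s the LF band vanishes and the feature errors out.

**EMG.** Only recordings at ≥ 512 Hz are analyzed (Nyquist for the 200-Hz
band edge). Per 2-s epoch: RMS, z-scored to PRE exactly as the EEG powers;
per period: MNF as above.

**Deltas** are always first-listed minus second-listed (MTI−PRE, POST−PRE,
MTI−POST), so a positive MTI−PRE value is an increase during the
intervention.

## Inference

The test is a two-sample permutation test of mean equality: statistic
`mean(x) − mean(y)`, two-sided, 1600 label permutations, with the add-one
correction `p = (1 + #{|T*| ≥ |T|}) / (1 + n_perm)` so a sampled p is never
zero; when `choose(n, nx) ≤ n_perm` all distinct splits are enumerated and
the exact proportion is returned. The exchangeable unit is the
per-recording period value (not the epoch), matching an analysis across all
patients and recordings; the two recordings of a patient are treated as
independent units, and epoch pooling is deliberately not offered as a
default. The test is unpaired even though periods are within-subject —
fidelity to the two-population comparison — while the reported descriptives
(mean and SD of change) are paired per recording. EEG contrasts are
Benjamini-Hochberg adjusted across the 8 electrodes within each band;
significance means adjusted p < 0.05. Per-comparison RNG seeds are derived
by hashing the global seed with the feature and pair labels, so results do
not depend on execution order. Note that BH adjustment is *not* idempotent
(re-adjusting adjusted values changes them); the invariants that do hold —
pointwise dominance, order preservation, monotonicity under adding a larger
p — are asserted in the test suite.

Clinical scores: VAS is compared PRE vs POST with one pair per recording
session (17 units); HADS first vs last per patient, excluding patients
without the last timepoint. Both per-session and per-patient VAS summaries
are computed, since the printed cohort means can be read either way; the
per-session reading reproduces them. Descriptive SDs of clinical scores use
the population (N) denominator — that is the convention under which the
published change SDs (1.55 VAS, 2.99 depression, 4.41 total) reproduce
exactly. Minimal clinically important differences (1.4 VAS points, 1.7
HADS points) are configuration constants, flagged on |mean change|.

## The synthetic-session generator

Every stage is validated against sessions with known ground truth:

* **EEG**: each channel is a sum over bands of band-limited Gaussian noise
  built by spectral shaping (frequency-domain construction, inverse
  transform, exact empirical rescaling), so the within-band power of period
  p is exactly `multiplier(p)` × the PRE base power (defaults 40/20/15/8/5
  µV² for Delta…FastBeta). Optional blink transients are biphasic sub-4-Hz
  pulses, largest frontally.
* **ECG**: `RR_n = meanRR + a_LF sin(2π f_LF t_n) + a_HF sin(2π f_HF t_n) +
  ε_n` with ε truncated at ±3 SD, a Mexican-hat QRS template (80 ms, 1 mV)
  at each cumulative peak time, additive white noise, and the true peak
  times returned for detector validation. Profiles that could push RR
  outside 300–1500 ms are rejected at construction so generator and cleaner
  cannot interact.
* **EMG**: Gaussian noise shaped by a Gaussian-in-frequency power envelope
  (SD 30 Hz, truncated to 20–200 Hz) whose centroid tracks the period
  target within ~2 Hz; RMS rescaled exactly per period.
* **Clinical**: integer VAS (0–10) and HADS (0–21) tables with configurable
  mean shifts, noise SDs and a missing-last fraction; out-of-range draws are
  clipped with a warning.

All generators are pure functions of (profile, seed) and restore the
caller's RNG state. The default study-level dataset
(`simulate_study_dataset()`) mirrors the cohort's availability — 9 patients,
17 sessions, 16 with ECG, 14 with analyzable EMG — and injects effects in
the directions reported for the cohort.

What the generator does **not** emulate: 1/f-continuum EEG background and
non-stationarity, true QRS morphology and ectopic beats, respiratory
coupling of the R-R series beyond fixed-frequency sinusoids, motion and
electrode artifacts other than injected test pulses, and any burn-specific
pathophysiology. Passing tests therefore demonstrate that the *pipeline*
recovers known effects under controlled conditions, not that the biological
conclusions transfer.

## Problem sizes used in tests

Simulation-based tests and the acceptance script run on scaled-down
sessions: 60/90/60-s periods for EEG/EMG checks, 120/180/120 s where the
tachogram's LF band is needed (the adaptive cutoff requires T > 80 s), and
8 recordings × 20 seeds for the EEG recovery/power simulations; these sizes
were chosen once as the smallest at which every estimator operates in its
intended regime. Two checks intentionally use the full 5/15/5-min periods:
the null mean-z envelope (|mean z| < 0.2 needs the full epoch count) and
nothing else. One property worth knowing when interpreting recovery
simulations: doubling one band's power genuinely leaks a small amount into
the adjacent band's integral at the shared edge (finite spectral window +
contiguous integration), so a strong Alpha effect at O1 is accompanied by a
real, consistently detected secondary SlowBeta effect at the same electrode.
The recovery criterion therefore asserts that the injected cell is
significant, positive, dominant in magnitude and unique within its band —
not unique across all 40 cells.

## Known limitations

* The BIDS reader supports BrainVision (binary float32/int16 and ASCII) and
  EDF with uniform per-signal rates; compressed or exotic variants error out
  explicitly.
* The automatic artifact mask is amplitude-based only; it will not catch
  low-amplitude muscle or electrode drift artifacts that visual inspection
  would.
* The ICA blink rule assumes blinks dominate the low-passed frontal mean;
  recordings without Fp1/Fp2 cannot be cleaned this way.
* HRV analysis assumes sinus rhythm; ectopy is handled only through the R-R
  bounds rule.
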