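# marphysio

Analysis pipeline for multimodal electrophysiology recorded **before,
during and after music-assisted relaxation (MAR) sessions** with burn
patients in intensive care. Each session carries three annotated periods —
baseline rest (PRE), the music-therapy intervention (MTI) and
post-intervention reincorporation (POST) — and three signal modalities:
8-channel EEG (Fp1, Fp2, T3, T4, C3, C4, O1, O2), single-lead ECG and
bipolar facial EMG. The package is written for researchers who want to
re-run, audit or extend this kind of pre/during/post physiological
analysis, and ships a synthetic-session generator with known ground truth
so every stage is testable without patient data.

## What it computes

* **EEG band power** — per 3-s epoch (1.5-s overlap) Welch PSD and
  composite-Simpson band power over Delta (1–4 Hz), Theta (4–8), Alpha
  (8–12), SlowBeta (12–18) and FastBeta (18–30), z-scored to the PRE
  baseline: `z = (x − μ_PRE)/σ_PRE`; topographic MTI−PRE and POST−PRE
  contrasts with permutation p-values, FDR-adjusted across electrodes
  within each band.
* **Heart-rate variability** — R-peak detection, R-R cleaning to
  [300, 1500] ms with linear interpolation, then per period: meanRR, STDRR,
  pRR50; Poincaré SD1/SD2 on PRE-normalized tachograms (SD1 ≡ RMSSD/√2
  exactly); LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) power of the 4-Hz
  cubic-spline-resampled tachogram as percentages of total power, with the
  adaptive lower cutoff `f_low = max(0.04, 12/T)` for windows under 5 min.
* **Facial-EMG tone** — 20–200 Hz band-pass with a 60-Hz notch comb, 2-s
  epoch RMS z-scored to PRE, and the period mean frequency (MNF, spectral
  centroid of the normalized mean PSD).
* **Inference** — two-sample permutation test of mean equality
  (H₀: μ₁ − μ₂ = 0, 1600 permutations, two-sided, exhaustive when
  enumerable) on per-recording period values, with Benjamini-Hochberg FDR
  where multiple electrodes are compared.
* **Clinical scores** — VAS pain (0–10, per session pre/post) and HADS
  anxiety/depression (0–21 each, first/last timepoint) summaries with
  permutation comparisons and minimal-clinically-important-difference flags
  (1.4 VAS points, 1.7 HADS points).
* **IO** — a BIDS-EEG-style reader/writer (BrainVision and EDF), tidy TSV
  result tables, and a JSON run summary with config hash and seed.

## Worked example

Recover a known muscle-tone effect from a synthetic EMG session in which
the spectral centroid drops from 120 Hz to 100 Hz during the intervention:

```r
library(marphysio)

prof <- emg_profile(centroid = c(pre = 120, mti = 100, post = 120))
g <- gen_emg_session(prof, durations = c(pre = 60, mti = 90, post = 60),
                     fs = 512, seed = 8)
s <- emg_session_summary(g$recording, g$segmentation)
subset(s$deltas, feature == "mnf")
#>       pair feature      delta
#> 2  mti-pre     mnf -19.053844
#> 4 post-pre     mnf   1.187101
#> 6  mti-post     mnf -20.240946
```

The −20 Hz injected shift is recovered as −19.1 Hz (MTI−PRE) with PRE and
POST essentially equal — the same pattern the cohort showed at a smaller
effect size. The clinical summaries of the study's own score table are one
call away:

```r
vas <- summarize_vas(study_clinical_table())
c(pre = vas$pre$mean, post = vas$post$mean, change = vas$change$mean,
  p = vas$p)
#>        pre       post     change          p
#>  2.0000000  1.2352941 -0.7647059  0.4234853
```

A full synthetic study (9 patients, 17 sessions, 16 with ECG, 14 with
analyzable EMG, effects injected in the cohort's reported directions) is
driven by the numbered scripts under `analysis/`:

```sh
Rscript analysis/01_simulate.R    # writes scratch/study_bids
Rscript analysis/02_analyze.R    # features + group stats -> results/analysis
Rscript analysis/03_clinical.R   # clinical summaries     -> results/
Rscript analysis/04_report.R     # figures from the tidy tables
```

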