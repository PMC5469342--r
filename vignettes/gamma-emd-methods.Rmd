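---
title: "Methods: gamma-band ERS from single-channel EEG via EMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-band ERS from single-channel EEG via EMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdgamma)
```

## The problem

Motor tasks induce gamma-band oscillations (30–60 Hz) over the motor
cortex. In scalp EEG these oscillations are microvolt-scale and buried
in broadband background activity, and because induced activity is
time-locked but not phase-locked to the cue, it can only be recovered
through power measures computed per trial, never through averaging of
the raw trace. The standard quantification is event-related
synchronization (ERS): with $GBA_m$ and $GBA_b$ the mean gamma-band
power in the motor and basal (resting) conditions,

$$\mathrm{ERS}(\%) = \frac{GBA_m - GBA_b}{GBA_b} \times 100 .$$

Negative values (motor below basal) are event-related
desynchronization. The ratio form makes ERS invariant to any common
gain — notably the attenuation introduced by referencing the active
electrode against a common reference, which affects both conditions
equally.

This package implements a single-channel pipeline in which the signal
is additionally decomposed by Empirical Mode Decomposition (EMD) before
spectral analysis. ERS is then computed three ways — from the
pre-processed signal itself, and from its first and second intrinsic
mode functions (ERS1, ERS2). Because EMD extracts the highest-frequency
oscillatory mode first, IMF1 acts as an adaptive high-pass filter: it
retains narrowband gamma activity while shedding the large
low-frequency background that otherwise dilutes the ERS ratio, which is
why ERS1 typically exceeds ERS when genuine gamma activity is present.

## Pipeline

1. **I/O** — recordings are read from EDF/EDF+ (or generated
   synthetically); all voltages are converted to microvolts.
2. **Pre-processing** — zero-phase Butterworth band-pass (1–100 Hz)
   and mains notch (49–51 Hz), epoching into 2-s trials, per-trial
   linear detrending, automatic artifact rejection.
3. **EMD** — per-trial sifting into at most five IMFs plus a residue.
4. **Spectral analysis** — multitaper (DPSS) PSD per trial; gamma-band
   activity is the mean PSD over the closed 30–60 Hz band.
5. **ERS and statistics** — per-trial GBAs are averaged within
   condition, the ERS ratio is formed per subject, hand and method, and
   methods are compared pairwise with a normality-gated paired test.

## Design choices and their rationale

### Pre-processing

The filter family and order are conventional choices: the band-pass is
a high-pass/low-pass Butterworth cascade of order 4 per edge and the
notch a band-stop of order 2, all applied forward–backward
(`filtfilt`). Zero phase matters because trial windows are defined
relative to the cue; a causal filter would shift oscillatory energy
across trial boundaries. Filtering is applied to the continuous
recording *before* epoching so that edge transients fall outside the
trials. On a steady tone the notch attenuates 50 Hz by more than 40 dB
while leaving 40 Hz within 0.1 % of its amplitude (both verified in the
test suite).

Artifact handling replaces interactive visual inspection with two
deterministic per-trial rules: peak amplitude above 100 µV, or any
sample-to-sample jump whose robust z-score (median/MAD over all trials'
first differences) exceeds 8. Both thresholds are conventional EEG
screening values and configurable; the point of the substitution is
reproducibility — the same input always yields the same set of
rejected trials, and the run log records the counts.

The basal recording has no cues, so it is segmented into consecutive
non-overlapping pseudo-trials of the same 2-s duration as the motor
trials. This gives basal and motor PSD estimates identical spectral
resolution and taper count, so the ERS numerator and denominator are
estimated with the same bias and variance structure.

### EMD

The decomposition follows the classical sifting scheme: find all local
extrema, interpolate maxima and minima separately with natural cubic
splines, subtract the envelope mean, and iterate until the candidate
qualifies as an IMF; then remove it and restart on the residue. Choices
the algorithm statement leaves open were fixed as follows.

* **Inner stopping rule.** Sifting of one IMF stops when the
  Cauchy-type criterion $\sum M^2 / \sum h^2 < 0.2$ is met *and* the
  candidate's extrema and zero-crossing counts (two boundary samples
  excluded at each end) differ by at most one, with a hard cap of 50
  sifts. The count condition is part of the IMF definition; the energy
  condition alone can stop one sift too early on noisy segments, which
  is exactly where the count condition still fails.
* **Outer stopping rules.** Extraction stops when the residue has at
  most one extremum, when the extracted component's (or residue's)
  energy falls below $10^{-6}$ of the input energy, or when five IMFs
  have been extracted. Five modes cover gamma through theta at these
  sampling rates; the cap is configurable.
* **Boundary handling.** The two extrema nearest each end are mirrored
  across the end sample before spline fitting. Without this the spline
  flares freely at the edges and the error concentrates in IMF1 —
  precisely the mode the gamma analysis uses.
* **Plateaus.** A run of equal samples between opposite slopes
  contributes its midpoint index as the extremum — a deterministic
  tie-break.
* **Sampling condition.** EMD separates a component cleanly only when
  the sampling rate is roughly five times the highest frequency of
  interest; `check_emd_sampling()` warns below `5 * f_max`. At 2048 Hz
  the 60 Hz band edge is sampled 34 times per cycle, comfortably above
  the condition.

The reconstruction identity $x = \sum_j \mathrm{IMF}_j + r_N$ holds to
machine precision by construction, whatever the stopping rules do, and
is asserted over random signals in the tests.

EMD is applied per 2-s trial (matching the per-trial GBA computation),
not to the continuous record; decomposing the continuous record is
possible via `emd()` directly but couples trials through the envelopes.

### Spectral estimation

PSDs use DPSS (Slepian) multitapers, computed from the canonical
symmetric tridiagonal eigenproblem with LAPACK's tridiagonal solver and
cached per configuration. The smoothing half-bandwidth defaults to
2 Hz, giving a time–half-bandwidth product of 4 and $2 \cdot 4 - 1 = 7$
tapers on 2-s trials — enough variance reduction to make single-trial
gamma power usable without washing out the 30 Hz-wide band. Trials too
short for one DPSS taper fall back to a single Hann taper.

Normalization is one-sided density: integrating the PSD over
$[0, f_s/2]$ recovers the signal variance (checked to 5 % on white
noise, and the band-integrated power of a tone of amplitude $A$ is
$A^2/2$). Gamma-band activity is the *mean* PSD over all bins in the
closed interval $[30, 60]$ Hz — a mean rather than an integral, and
closed endpoints, so results are bit-reproducible given a trial length.

### Statistics

Subject-level ERS uses means-then-ratio: per-trial GBAs are averaged
within condition first and the ratio of the two means is taken. The
alternative (averaging per-trial ratios) weights noisy low-power trials
heavily and has no counterpart in how basal activity is measured (a
single long recording, not paired with motor trials).

Method comparisons are paired per subject. Each sample first passes a
normality gate at $\alpha = 0.05$: the Lilliefors-corrected
Kolmogorov–Smirnov test by default, because the Gaussian parameters are
estimated from the same data and the plain KS test is anti-conservative
in that situation (the uncorrected variant remains available). Gaussian
pairs use the paired Student t-test, otherwise the Wilcoxon signed-rank
test; identical samples (all differences zero) report $p = 1$ by
convention so degenerate fixtures are well-defined. No
multiple-comparison correction is applied — the comparison table has
three pairs per hand and readers can apply their own.

## The synthetic generator

No public dataset accompanies this kind of experiment, so the package
generates its own: per subject a basal recording and a motor recording
of contiguous 2-s trials (cued right-hand block then left-hand block),
built from

* **1/f background** — Gaussian noise spectrally shaped to slope −1
  over 1–100 Hz, scaled to a time-domain σ (default 10 µV): the
  simplest surrogate with EEG-like spectral falloff;
* **rhythms** — fixed sinusoids at 10 Hz (5 µV) and 20 Hz (2 µV), so
  that IMF2/IMF3 have realistic content to absorb;
* **gamma component** — a Hann-windowed burst per trial with a fresh
  uniform random phase (induced, non-phase-locked activity). Basal
  pseudo-trials carry the same burst type at spontaneous power
  $A_b^2/2$ (default $A_b$ = 1 µV equivalent-tone amplitude); motor
  trials carry it scaled so the gamma power ratio is exactly
  $1 + e/100$ for ground-truth ERS $e$.

Using the same burst waveform class in both conditions is a deliberate
deviation from "continuous basal tone, motor burst": DPSS tapers weight
the trial center, so a center-concentrated burst measured against a
continuous tone reads ~17 % high and the pipeline would systematically
overestimate ERS through no fault of its own. With identical envelopes
the taper weighting cancels exactly in the ratio, making the power
ratio a ground truth for *any* quadratic spectral estimator — and
spontaneous gamma is bursty in real EEG anyway.

Cohorts draw per-subject true ERS from a normal distribution
(default SD 20 %) truncated above −100 %, with per-subject seeds derived
from one master seed; the same seed reproduces every sample bit for bit.

### Fixture conditions used in validation

The in-band background contaminates the ERS denominator: with gamma
burst power $A^2/2$ and 1/f background of variance $\sigma^2$ over
1–100 Hz, the background-to-gamma band-power ratio in 30–60 Hz is
approximately $0.3\,\sigma^2/A^2$, and the estimated ERS shrinks by the
factor $1/(1 + 0.3\,\sigma^2/A^2)$. Two condition sets follow from this
analysis (made before the validation thresholds were ever run, and then
frozen):

* **Recovery / null conditions** ($\sigma = 1$ µV, $A_b = 2.5$ µV,
  40 Hz): bias factor ≈ 0.95, so ground-truth recovery is essentially
  unbiased and a true null stays a null. Used to check that a 50 %
  effect is recovered within its CI95 and that a 0 % effect is retained.
* **Headline conditions** ($\sigma = 10$ µV, rhythms on, $A_b = 2$ µV,
  45 Hz): the background dominates the band (bias factor ≈ 0.2), which
  is the regime the EMD filter is for — IMF1 sheds most of the
  background and ERS1 moves far closer to the truth than raw ERS.
  Used to check the direction and significance of the ERS1 > ERS
  effect.

Validation runs use scaled-down sizes — 10 subjects, 20 motor trials
per hand, 1 min of basal recording — rather than the emulated
experiment's 25 subjects, 100 trials per hand and 18 min of basal
activity; the generator's defaults keep the full-size values.

### What passing these checks does and does not show

The generator produces stationary background, pure sinusoidal rhythms
and a single narrowband gamma component at a known frequency. Real EEG
has non-stationary background, broadband gamma whose center varies
between subjects (which is exactly why gamma may land in IMF2 rather
than IMF1 for some subjects), ocular and muscular artifacts with
structured morphology, and reference/electrode drift. Passing the
recovery checks therefore demonstrates that the *pipeline arithmetic*
is correct and calibrated, not that effect sizes from real recordings
are unbiased. The artifact-rejection rules here are screening
heuristics, not substitutes for EOG/EMG-informed cleaning.

## Known limitations

* IMF assignment is adaptive: in subjects whose high-frequency content
  sits above 60 Hz, gamma lands in IMF2 and ERS1 underestimates the
  effect — per-subject inspection of IMF mean frequencies
  (`mean_frequency()`) is advisable before pooling.
* The sift cap (50) can, rarely, leave a noise-dominated deep IMF that
  misses the extrema/zero-crossing criterion by 2; raising
  `max_sifts_per_imf` trades runtime for strictness.
* The EDF writer stores 1-s records and zero-pads traces that are not
  a whole number of seconds (keeping the sampling rate exact); it
  writes single-channel files only.
* Ensemble and multivariate EMD variants, time-resolved spectrograms
  and high-gamma (60–200 Hz) analysis are out of scope.
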