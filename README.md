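# emdgamma

Gamma-band EEG analysis by Empirical Mode Decomposition.

`emdgamma` quantifies motor-task-induced gamma-band activity (GBA,
30–60 Hz) in **single-channel** EEG and measures event-related
synchronization (ERS) three ways: from the pre-processed signal, and
from its first and second intrinsic mode functions (IMFs). It is aimed
at electrophysiology researchers who want a reproducible, scriptable
alternative to interactive EEG toolchains for single-electrode gamma
work — portable/ambulatory setups, quick clinical screens, BCI
prototyping.

## The method

A recording is band-pass filtered (1–100 Hz), notch filtered
(49–51 Hz), epoched into 2-s trials, detrended and screened for
artifacts. Each trial is then decomposed by EMD — iterative sifting
against cubic-spline envelopes through the local extrema — into
intrinsic mode functions ordered from high to low frequency:

```
x(t) = IMF1(t) + IMF2(t) + ... + IMFN(t) + r_N(t)
```

Per trial, gamma-band activity is the mean multitaper (DPSS) power
spectral density over 30–60 Hz, computed from `x(t)` itself and from
IMF1 and IMF2. With `GBAm` and `GBAb` the condition means of motor and
basal trials:

```
ERS(%)  = (GBAm  - GBAb ) / GBAb  * 100      (raw signal)
ERS1(%) = (GBAm1 - GBAb1) / GBAb1 * 100      (IMF1)
ERS2(%) = (GBAm2 - GBAb2) / GBAb2 * 100      (IMF2)
```

Because EMD extracts the fastest oscillations first, IMF1 behaves as an
adaptive high-pass filter: it keeps narrowband gamma but drops the
low-frequency background that inflates `GBAb`, so ERS1 > ERS whenever
real gamma activity is present. Methods are compared per subject with a
paired test gated by a Lilliefors normality check (Student t if both
samples Gaussian, Wilcoxon signed-rank otherwise).

A synthetic-data module generates full experiments (1/f background,
alpha/beta rhythms, non-phase-locked gamma bursts) with known
ground-truth ERS, so every stage is testable without external data.

## Worked example

Simulate a 10-subject cohort whose gamma bursts (45 Hz, ground-truth
ERS 100 %) are buried in strong 1/f background, then run the full
pipeline for all three methods:

```r
library(emdgamma)

cfg <- list(
  synth = list(n_subjects = 10, between_subject_sd = 20,
               n_trials_per_hand = 20, basal_minutes = 1,
               background_sigma_uV = 10, gamma_basal_amp_uV = 2,
               gamma_freq_hz = 45, ers_true_percent = 100),
  methods = c("original", "imf1", "imf2"),
  seed = 7)

res <- run_pipeline(cfg)
aggregate(ers_percent ~ method + hand, res$ers, mean)
#>     method  hand ers_percent
#> 1     imf1  left   22.691432
#> 2     imf2  left    2.101555
#> 3 original  left   15.139820
#> 4     imf1 right   24.383921
#> 5     imf2 right    2.722845
#> 6 original right   16.118628

res$comparisons
#>    hand             pair  n     test           p
#> 1 right original vs imf1 10 paired-t 0.002372833
#> 2 right original vs imf2 10 paired-t 0.018389997
#> 3 right     imf1 vs imf2 10 paired-t 0.009365107
#> 4  left original vs imf1 10 paired-t 0.001780445
#> 5  left original vs imf2 10 paired-t 0.004337205
#> 6  left     imf1 vs imf2 10 paired-t 0.002761903
```

The background dominates the 30–60 Hz band here, so the raw-signal ERS
(~16 %) badly underestimates the true 100 % effect. IMF1 filtering
sheds most of that background and raises the estimate to ~24 % with a
significant paired improvement in both hands, while IMF2 — which holds
the beta-range content — shows almost no effect. This ordering
(ERS1 > ERS > ERS2) is the expected signature when the induced gamma
component lies in-band.

A command-line front end is installed with the package
(`system.file("cli", "gbaemd", package = "emdgamma")`) with
`run`, `simulate` and `decompose` subcommands over the same functions.

## Package layout

- `R/recording.R`, `R/edf.R` — recording/trial containers, EDF/EDF+ I/O
- `R/preprocess.R` — filtering, detrending, artifact rejection
- `R/emd.R` — extrema, envelopes, sifting, IMF criteria
- `R/spectral.R` — DPSS tapers (LAPACK tridiagonal solver in `src/`),
  multitaper PSD, band power, per-trial GBA
- `R/ers.R` — ERS, grand averages, normality-gated paired comparisons
- `R/synthgen.R` — synthetic subjects and cohorts
- `R/pipeline.R` — end-to-end orchestration and CSV outputs
- `vignettes/gamma-emd-methods.Rmd` — model, assumptions, design
  decisions and limitations
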