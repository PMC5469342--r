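Package: emdgamma
Title: Gamma-Band EEG Analysis by Empirical Mode Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Single-channel EEG analysis of motor-task gamma-band activity
    (30-60 Hz). Provides a minimal EDF/EDF+ reader and writer, a
    pre-processing chain (zero-phase band-pass and notch filtering, linear
    detrending, threshold-based artifact rejection), a from-scratch
    Empirical Mode Decomposition (cubic-spline envelope sifting into
    intrinsic mode functions), multitaper (DPSS) power spectral density
    estimation, event-related synchronization (ERS) computed from the raw
    signal and from the first two intrinsic mode functions, a paired
    group-comparison protocol with a Lilliefors normality gate, and a
    synthetic-EEG generator with known ground-truth ERS for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: signal, nortest, yaml, stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
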