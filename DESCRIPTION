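Package: vfwave
Title: Ventricular Fibrillation Waveform Analysis via Amplitude Spectral Area
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the ventricular fibrillation (VF) ECG waveform by the
    amplitude spectral area (AMSA): sliding-window Tukey-tapered amplitude
    spectra (2.1 s frames every 0.5 s), the summed amplitude-frequency
    product over 2-48 Hz, and per-minute averaging. Includes a calibrated
    synthetic VF cohort generator reproducing a prescribed minute-by-minute
    AMSA trajectory with persistent per-subject offsets and pulsatile
    extracorporeal-circulation artifacts, derived coronary hemodynamic and
    metabolic quantities (coronary perfusion pressure, Fick oxygen delivery
    and consumption, lactate flux, veno-arterial PCO2 gradient), and the
    statistical stage used on such cohorts: repeated-measures ANOVA,
    Holm-Sidak pairwise comparisons, Pearson correlation and simple linear
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
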