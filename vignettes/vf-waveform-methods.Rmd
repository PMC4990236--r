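---
title: "Methods: AMSA waveform analysis, synthetic VF cohorts, and the statistical stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AMSA waveform analysis, synthetic VF cohorts, and the statistical stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfwave)
```

## The spectral model

The amplitude spectral area treats a short segment of the VF ECG as
quasi-stationary and summarizes its one-sided amplitude spectrum by the
amplitude-weighted frequency sum

$$\mathrm{AMSA} = \sum_{2 \le F_i \le 48} A_i F_i \quad [\mathrm{mV\cdot Hz}],$$

where $A_i$ is amplitude (the square root of power) at bin frequency $F_i$.
The pipeline slides a `window_s = 2.1` s frame every `step_s = 0.5` s,
removes each frame's mean, applies a Tukey taper, transforms with the DFT,
and averages the per-frame AMSA over 60-s epochs anchored at VF onset
(minute $m$ covers $[(m-1)\cdot 60, m\cdot 60)$ seconds, frames binned by
their window-center timestamp). A trailing incomplete minute is reported
separately and never averaged into the complete-minute means.

Assumptions worth making explicit:

* **Quasi-stationarity over 2.1 s.** VF spectral content drifts over tens of
  seconds; within one frame it is treated as fixed.
* **Uniform sampling** with all band content below Nyquist
  (`band_hi` $\le f_s/2$ is enforced at analysis time).
* **Amplitude linearity.** AMSA is linear in signal amplitude, which the
  test suite asserts to floating tolerance; anything that scales the ECG
  (electrode gain, body habitus) scales AMSA identically.

## Numerical choices

Several conventions are under-determined by the definition above; the
package fixes them as follows and exposes each in `spectral_config()`.

* **Amplitude normalization.** One-sided amplitudes use coherent-gain
  normalization $A_i = (2/\sum w)\,|X_i|$ (half that at DC and Nyquist),
  with $\sum w$ the sum of taper coefficients. A unit-amplitude in-bin
  sinusoid under a rectangular taper then reads 1 mV at its bin, which makes
  the mV·Hz unit literal: that sinusoid's AMSA equals its frequency. This is
  the property the oracle tests pin down.
* **No zero-padding.** Frames of $N = \mathrm{round}(2.1 f_s)$ samples give
  bin spacing $f_s/N$ (~0.48 Hz at 250 Hz). Because AMSA is a *sum* rather
  than an integral, its magnitude depends on bin width; comparisons of
  absolute AMSA values across devices or window conventions are therefore
  approximate, and all acceptance quantities here are produced and consumed
  under this one convention.
* **Tukey taper fraction** defaults to `tukey_alpha = 0.5` (flat middle
  half, cosine-tapered quarters). The taper fraction is a free parameter of
  the published method; it affects absolute AMSA through $\sum w$ and
  leakage, so it is part of the recorded run configuration.
* **Band edges inclusive.** "2 to 48 Hz" is read inclusively at both ends.
  With non-pathological sampling rates, bins rarely land exactly on an edge,
  so this choice is essentially cosmetic — but it is fixed and tested.
* **Per-frame mean removal** (default on) keeps DC from leaking into the
  2 Hz edge; the tests check a constant offset changes AMSA by
  < 1e-6 relative.
* **Artifact flagging.** The published analysis discarded frames corrupted
  by pump pulsatility but states no rule. The package flags a frame invalid
  when sub-band amplitude (below `band_lo`) exceeds half the total spectral
  amplitude — a deliberately simple energy-dominance rule. All-zero frames
  are valid (ratio defined as 0). Minutes whose frames are all invalid
  yield `NA` means.

## The synthetic cohort generator

No waveform model accompanies the published trajectory, so the generator is
an engineering choice: white Gaussian noise, band-pass filtered (4th-order
Butterworth, zero-phase) to `center_freq ± bandwidth/2` (default 9 ± 3 Hz,
inside the AMSA band), then multiplied by the piecewise-linear interpolation
of the profile knots between knot-minute centers (constant beyond the ends).
Filtered noise has a roughly flat in-band spectrum, so AMSA is controllable
purely through gain — which is what makes closed-loop calibration work.

**Calibration is closed-loop against the pipeline, not analytic**: the
generator measures the minute-mean AMSA that one unit of signal amplitude
produces, by running `amsa_timeseries()` on a fixed-seed 180-s reference
realization of the same filtered process, and scales the envelope
accordingly. This makes the generator robust to every windowing and
normalization decision above. The reference realization is deliberately
*not* the subject's own noise: self-calibration would pin each record's
anchor minute to its target exactly, deleting the natural sampling noise
there and distorting between-subject correlation structure — visible as
spurious anchor correlations in null cohorts. The measured unit response is
cached per (sampling rate, band, spectral config); caching changes speed
only.

**Between-subject variability** is a persistent multiplicative lognormal
offset $s_j = e^{\varepsilon_j}$, $\varepsilon_j \sim N(0, \sigma^2)$ with
$\sigma = 0.25$ by default, drawn once per subject and applied to the whole
recording. Multiplicative because AMSA is amplitude-proportional and
strictly positive; persistent because the phenomenon being emulated is a
subject-specific AMSA level that holds from the first minute of VF through
resuscitation. With $\sigma = 0.25$ and $n = 16$, anchor-minute correlations
approach 1; with $\sigma = 0$ they collapse to the null distribution of
Pearson's $r$ at $n = 16$ — both checked in the acceptance suite.

**Pulsatile artifacts** are smooth unipolar raised-cosine pulse trains at a
sub-2 Hz rate, amplitude expressed relative to the record's RMS, added from
a given onset. Rates at or above the 2 Hz band edge are rejected, since the
phenomenon being modeled is by construction sub-band.

**What the generator does not emulate**: ECG morphology (no QRS-like
structure, no restitution or spiral-wave dynamics), spectral peak drift
within a minute, heteroscedastic or non-lognormal subject effects,
electrode noise, and any coupling between AMSA and physiology. Passing the
profile-recovery tests therefore shows the *pipeline* is correct and the
generator calibrated — not that real VF behaves like filtered noise.

### Default study conditions

The default profile knots are the published cohort means (mV·Hz):
11.9 (minute 1), 6.9 (6), 7.0 (8), 12.8 (14), 11.9 (18), 14.3 (19),
9.1 (22). The true within-subject shape *between* those minutes is unknown;
linear interpolation is a stated assumption, not data. Default cohort sizes
follow the study: 16 subjects for low-flow analyses, 8 where the scaled-down
profile-recovery check is run. Sampling rate is not stated in the source
analysis; the package accepts any rate with the band below Nyquist, uses
250 Hz as the canonical unit-test rate, and runs cohort-scale simulations at
100 Hz (Nyquist 50 Hz still covers the 48 Hz edge) — chosen once as the
problem size that keeps multi-seed cohort simulations (100 seeds × 16
subjects × 17 min) comfortably tractable on one CPU.

## The physiology stage

All derived quantities are elementwise over per-timepoint panels:
CPP = mean aortic − mean right-atrial pressure (negative values reported
as-is); MDO₂ = flow × CaO₂; MVO₂ = flow × (CaO₂ − CvO₂); extraction =
(CaO₂ − CvO₂)/CaO₂; lactate flux = flow × (arterial − venous), **positive =
consumption** (stated in an output attribute because prose conventions
differ); PCO₂ gradient = venous − arterial. Flow is kept in its reported
unit (typically % of baseline) and never converted to absolute ml/min: the
baseline absolute flow is not part of the deliverable data, so Fick products
are meaningful as ratios to their own baseline, via
`percent_of_baseline()`. Where it is ambiguous whether a published
"% of baseline" Fick quantity renormalized flow and content jointly or flow
alone, the package computes the joint product and normalizes that to its own
baseline — the self-consistent reading.

## The statistical stage

* **Descriptives**: mean, SD ($n-1$), SEM = SD$/\sqrt n$ per timepoint.
* **One-way repeated-measures ANOVA**: the classical within-subject
  decomposition — time effect on $k-1$ df against the subject-by-time
  residual on $(n-1)(k-1)$ df — obtained from the additive two-way fixed
  `aov()` fit, whose time stratum is algebraically identical. **No
  sphericity correction by default**, matching the behavior of the
  commercial package used for the original analyses; Greenhouse–Geisser is
  available as an option (`gg_correction = TRUE`). Degenerate tables are
  resolved in a fixed order: zero time sum-of-squares → $F = 0, p = 1$
  (even if the residual is also zero); nonzero time effect with zero
  residual → $F = \infty, p = 0$, flagged degenerate. Subjects missing any
  timepoint are excluded listwise and counted.
* **Holm–Šidák step-down**: the $i$-th smallest of $m$ p-values is tested at
  $1-(1-\alpha)^{1/(m-i+1)}$; once one fails, all larger fail. Adjusted
  p-values $1-(1-p)^{m-i+1}$ are made monotone and capped at 1. Implemented
  directly (base R's `p.adjust` offers Holm–Bonferroni but not the Šidák
  variant); significance is reported at the two tiers used in figure
  annotation (0.05 and 0.001). The comparison family follows the published
  figures: every timepoint against a reference column, via
  `pairwise_vs_reference()`.
* **Correlations and regression**: Pearson $r$ with the two-sided $t$ test
  on $n-2$ df (pairwise-complete deletion), OLS simple regression, and the
  anchor-minute variability table, which records per-row errors (e.g. a
  constant column) without aborting remaining rows. Two-sided p-values
  throughout.

## Problem sizes and tolerances

Unit tests validate spectra against a term-by-term DFT oracle at 1e-9
relative on 100 random segments ($N \in [64, 1024]$), the ANOVA against a
textbook sum-of-squares oracle at 1e-10, and the null type-I error of the
repeated-measures test over 2,000 simulated 16 × 4 tables (accepted in
[0.03, 0.07] at $\alpha = 0.05$). Profile recovery is asserted within 10%
relative at every knot for an 8-subject offset-free cohort — the tolerance
reflects generator sampling noise (~2–3% per minute mean) plus calibration
noise, not pipeline error, which the oracle tests bound nine orders of
magnitude tighter.

## Known limitations

* Absolute mV·Hz values are convention-dependent (bin width, taper, window
  length); only within-convention comparisons are meaningful.
* The artifact detector is an energy-ratio heuristic; it will miss in-band
  artifacts (e.g. 50/60 Hz mains is outside its scope entirely) and has no
  notion of electrode dropout.
* The generator's linear-interpolation envelope cannot represent
  within-minute dynamics (e.g. the abrupt post-shock transients).
* `read_physio_table()` reads CSV; spreadsheet sources must be exported to
  CSV first.
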