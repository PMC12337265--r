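---
title: "Mapping physiological brain pulsations: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping physiological brain pulsations: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mregpulse)
```

## Scope

`mregpulse` quantifies physiological brain pulsations — cardiac,
respiratory and very-low-frequency (VLF) vasomotor oscillations — in
fast fMRI (MREG) time series sampled at ~10 Hz, where cardiac signal is
resolved without aliasing. Per voxel it computes three biometrics in
each physiological band, then carries subject maps through
permutation-corrected group inference, a mutual-ROI ROC stage, and an
RMSSD heart-rate-variability model. Synthetic generators (cohort,
pulsatile-flow phantom, photoplethysmogram) provide ground truth so
every stage is testable without clinical data.

## Signal model and per-voxel biometrics

The working model for a voxel time series is

$$s_v(t) = m_v\Big(1 + \sum_b a_{bv}\,\sin(2\pi f_b t + \phi_{bv})\Big) + \varepsilon_v(t),$$

a mean level $m_v$ modulated by one near-sinusoidal component per
physiological band plus wide-band noise. The three biometrics are:

* **CV (coefficient of variation)** — temporal SD over temporal mean of
  the band-filtered signal with the voxel mean reinjected:
  $\mathrm{CV} = \sigma_{band}/\mu$. The SD uses the $n-1$ denominator.
  For a noise-free sinusoid of relative amplitude $a$,
  $\mathrm{CV} = a/\sqrt{2}$.
* **SP (spectral power)** — the sum of periodogram power over the band's
  frequency bins.
* **SE (spectral entropy)** — Shannon entropy of the full-band
  (0.008–5 Hz) normalized power distribution,
  $-\sum_k p_k \ln p_k / \ln B$ with $B$ the number of bins, so
  $\mathrm{SE} \in [0, 1]$: 0 for a single line, 1 for a flat spectrum.
  Division by $\ln B$ makes values comparable across recording lengths;
  `se_map(..., normalize = FALSE)` returns raw nats.

All spectra use one periodogram convention throughout the package:
$P_k = |X_k|^2 / N$, one-sided ($k = 0 \ldots N/2$). Under it a unit
sinusoid on an exact bin contributes $N/4$ to that bin, and Parseval's
identity reads $\sum_t s_t^2 = P_0 + 2\sum_{mid} P_k + P_{Nyq}$. The
tests pin this convention; CV and SP are linked through it by
$\mathrm{CV}^2 \mu^2 (N-1) \approx 2\,\mathrm{SP}_{band}$ for a
band-limited signal.

### Frequency bands

| band | range (Hz) | source |
|---|---|---|
| VLF (vasomotor) | 0.008–0.1 | fixed |
| respiratory | peak ± 0.05 | per-subject spectral peak in 0.12–0.6 |
| cardiac | peak ± 0.05 | per-subject spectral peak in 0.6–1.8 |
| full band | 0.008–5 | fixed (5 Hz = Nyquist at 10 Hz) |

`resolve_bands()` finds the respiratory and cardiac peaks in a mean
spectrum and builds the ±0.05 Hz bands; `band_from_peak()` refuses bands
that would cross 0 or Nyquist.

### Filtering

Band-pass filtering is zero-phase frequency-domain masking: FFT, zero
every bin outside the band (including DC), inverse FFT, then reinject
the pre-filter voxel mean so CV's denominator is the raw mean signal.
This is exactly equivalent to least-squares projection onto the kept
Fourier basis (a property the tests verify against an independent
projection oracle). The high-pass in `trim_and_highpass()` removes bins
below 0.008 Hz after discarding the first 180 frames (18 s at 10 Hz),
the saturation-transient convention for these acquisitions; the
pre-trim mean per voxel is stored in `meta$voxel_mean`.

## Preprocessing and quality control

* `spatial_smooth()` — separable Gaussian, FWHM 5 mm default on 3 mm
  voxels; truncated at 4 SD with per-row renormalization so edge voxels
  keep unit kernel mass.
* `motion_qc()` — four exclusion layers on framewise displacement:
  maximum absolute > 1.5 mm, maximum relative > 0.5 mm, mean absolute
  > 0.6 mm, mean relative > 0.07 mm. Comparisons are strict, so a
  subject exactly at a threshold is retained.
* `respiratory_overlap_qc()` — excludes subjects whose respiratory band
  (peak ± 0.05 Hz) would overlap the VLF band (fail iff peak − 0.05 <
  0.1 Hz, with a 1e−9 guard against floating-point misclassification at
  the exact boundary).
* `despike_mad()` — optional k·MAD clipping (default k = 6, off by
  default): the synthetic data are spike-free, so despiking is a
  documented divergence left to the user for spiky acquisitions.

## Group inference

`fit_glm_contrast()` fits, per voxel, an ordinary-least-squares model
with one intercept per group plus centered nuisance covariates (age,
sex) and returns the t statistic of a named group contrast; with two
groups and no covariates this reduces exactly to the pooled-variance
two-sample t test.

`permutation_fwe()` controls family-wise error with the max-statistic
permutation scheme under **Freedman–Lane** nuisance handling: the data
are residualized on the nuisance-only model, residual rows are permuted,
the full model is refit, and the maximum (TFCE-enhanced) statistic per
permutation forms the null. Corrected
$p_v = (1 + \#\{\max^{(b)} \ge e_v\}) / (1 + n_{perm})$, so the
smallest attainable p is $1/(1+n_{perm})$ and the test is never
anti-conservative by construction. The test is one-sided in the
direction of the supplied contrast; for the opposite tail, negate the
contrast. (Running both tails at $\alpha$ each would test a union of
two $\alpha$-level tests, which is why the calibration suite checks a
single direction.)

**TFCE** (threshold-free cluster enhancement):
$\mathrm{TFCE}(v) = \sum_{h} e_v(h)^{E} h^{H}\, dh$ with $H = 2$,
$E = 0.5$, 100 integration steps ($dh = \max/100$) and 26-connectivity
clusters, implemented in C++ and cross-checked in the tests against a
brute-force igraph component-labelling oracle. A single unit-height
voxel enhances to $\sum_{s=1}^{100} (s/100)^2 / 100 \approx 1/3$, a
closed form the acceptance suite pins.

Significant-voxel extents are reported through
`voxels_to_volume_cm3()`: $n \cdot 27 / 1000$ cm³ for 3 mm voxels,
rounded to whole cm³ at or above 1 and one decimal below 1 (so 16,099
voxels → 435 cm³ and 28 voxels → 0.8 cm³).

## Mutual-ROI stage

`mutual_roi_analysis()` intersects the pairwise significant masks into
the *mutual difference mask*, averages each subject's biometric inside
it, and then:

* **ROC AUC** by the Mann–Whitney pair count,
  $(\#\{a<b\} + 0.5\#\{a=b\})/(n_a n_b)$ — the probability a value from
  the hypothesized-higher group exceeds one from the other.
* A normality gate: Shapiro–Wilk per group; any rejection routes to
  Kruskal–Wallis with **Dunn's** post hoc on the pooled mid-ranks
  (tie-corrected variance, Holm–Bonferroni step-down adjustment — the
  classical large-sample z form, not the rank-biserial or Conover
  variants), otherwise one-way ANOVA with Tukey HSD.

## HRV

`detect_beats()` finds PPG beats as maxima of first difference on each
pulse's rising limb (candidates from a smoothed trace with a 0.3 s
refractory period). `rmssd()` implements
$\sqrt{\tfrac{1}{N-1}\sum (RR_{i+1}-RR_i)^2}$. `hrv_qc()` applies the
5% rule: a recording is excluded iff
(misses + false detections)/#reference **exceeds** 5% — exactly 5%
passes. `medication_model()` fits `rmssd ~ medication + age + sex` by
OLS and reports the medication coefficient with its normal-theory CI.

## Synthetic generators

The generators are the package's study conditions: their defaults are
fixed design choices, not tuning knobs.

**Cohort** (`simulate_cohort()`): 12×12×12 grids, 10 Hz, 300 s,
baseline 100, band amplitudes 5% (VLF, 0.05 Hz), 5% (respiratory,
0.3 Hz), 10% (cardiac, 1.0 Hz), unit white noise, per-voxel random
phases, per-subject lognormal amplitude jitter (SD 0.1 on the log
scale) emulating inter-individual pulsation strength. Group effects are
voxel-box amplitude multipliers; `cohort_effect_mask()` returns the
exact ground-truth effect region. A `transform` argument applies a
per-subject pipeline immediately so large cohorts never hold raw 4D
data for more than one subject at a time.

**Pulsatile-flow phantom** (`simulate_phantom()`): a water-channel ROI
(8×8×9 voxels in a 12³ grid) scanned under an inactive pump and three
flow states, 462 steady-state samples per state at 10 Hz. Each flow
state injects a principal line at a frequency proportional to flow
speed (1.47, 2.93, 4.4 Hz — the fastest state lands on the 4.4 Hz
principal peak such a phantom shows at 10 Hz sampling), a first-degree
harmonic, state-dependent broadband power (standing in for
heterodynes/turbulence) and, in *every* state including baseline, a
1.0 Hz scanner helium-pump artifact line. Components above Nyquist fold
to $|f - f_s\,\mathrm{round}(f/f_s)|$ (`alias_frequency()`), so e.g. a
5.6 Hz component sampled at 10 Hz appears at 4.4 Hz.

The default amplitudes were derived *a priori* from the target
signal-to-noise regime rather than fitted: a line of amplitude
$A\sigma$ on noise of variance $\sigma^2$ multiplies the ROI full-band
SP by roughly $1 + A^2/2$, so matching median SP ratios of order
14/25/28 gives $A = \sqrt{2(r-1)} \approx$ 5.1/6.9/7.3, and broadband
SDs follow the same algebra from background-SP ratios of order
12.8/3.1/1.6. The acceptance suite asserts only the qualitative
monotone pattern (CV and SP strictly increasing with flow, SE dropping
from baseline to the first flow state); no numeric target depends on
these defaults.

**PPG** (`simulate_ppg()`): beats paced by RR intervals
$\mathcal{N}(1.0, 0.03^2)$ s at 100 Hz for 300 s, each beat a
half-cosine upstroke plus exponential decay. Reported ground-truth
`beat_times` are the instants of maximal template upslope — the same
fiducial the detector estimates — so detection accuracy can be measured
to single-sample precision, and `true_rmssd` is the RMSSD of the
realized RR sequence.

## Calibration problem sizes

The null-calibration and effect-recovery suites are the package's own
design (desk-scale, one CPU): 200 null cohorts of two n = 10 groups on
8×8×8×600 grids with 250 permutations must give a family-wise rejection
rate in [0.02, 0.10] at $\alpha = 0.05$; an injected cardiac ×1.5
amplitude effect in a 4×4×4 box (n = 13 vs 21, mirroring a
patient-vs-control design) must be recovered with ≥ 80% sensitivity and
≤ 5% false positives outside the box. All seeds are fixed in the test
code and were chosen before the suites were run.

## Worked example

```{r example, eval = FALSE}
band <- frequency_band(0.95, 1.05, "cardiac")
pipe <- function(vol) cv_map(bandpass_with_mean(
  trim_and_highpass(vol, n_trim = 0), band))

box <- list(x = c(5, 8), y = c(5, 8), z = c(5, 8))
specs <- list(
  control = subject_sim_spec(grid = c(8, 8, 8), duration_s = 60),
  sleep   = subject_sim_spec(grid = c(8, 8, 8), duration_s = 60,
    regions = list(list(box = box, band = "cardiac", multiplier = 1.5))))
co <- simulate_cohort(specs, c(10, 10), seed = 1, transform = pipe)

res <- permutation_fwe(co$subjects, co$design,
                       c(sleep = 1, control = -1),
                       n_perm = 250, seed = 2)
significant_mask(res, alpha = 0.05)$volume_cm3
```

## Limitations

* The generators emulate amplitude structure and spectral geometry, not
  hemodynamics: no HRF, no spatial autocorrelation of noise, no motion.
  They validate the measurement chain, not physiological realism.
* Clinical-scale effects (extents, AUCs and p values of real cohorts)
  are not reproducible without the clinical data; acceptance rests on
  analytic conversions, synthetic ground truth and closed forms.
* The brick-wall FFT filter assumes approximate stationarity within the
  analyzed segment; drifting cardiac rates widen the true band beyond
  peak ± 0.05 Hz.
* Sub-resolution drift (below one frequency bin) cannot be fully
  removed by DC/bin masking; the 18 s trim mitigates the dominant
  transient instead.
* The medication model is a plain OLS adjustment; no weighting or
  randomization-based sensitivity analysis is included.
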