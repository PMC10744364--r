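---
title: "Frontal-temporal spectral power ratios as qEEG markers of FTD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frontal-temporal spectral power ratios as qEEG markers of FTD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftdqeeg)
```

## The problem and the marker family

Frontotemporal dementia (FTD) is characterized by degeneration of the
frontal and temporal lobes, yet single-band, single-lobe quantitative EEG
measures (frontal theta power, temporal alpha power, and so on) have been
inconsistent discriminators of FTD against healthy controls. The marker
family implemented here is the set of *inter- and intra-lobar spectral
power ratios*: the absolute average band power of a frequency band in the
frontal (F) or temporal (T) lobe divided by the band power of another
(lobe, band) cell. With five canonical bands — delta [0.5, 4], theta
(4, 8], alpha (8, 13], beta (13, 30], gamma (30, 45] Hz — there are
`5 x 5 = 25` F/T ratios and `5 x 4 = 20` within-lobe ratios for each
lobe: 65 candidate markers per subject, written `F-theta/T-alpha`,
`T-beta/T-gamma`, and so on.

The package implements the complete analysis around this family:

1. **Band powers** per lobe under several Welch/FFT parameterizations
   (`spectral_params()`, `lobar_band_power()`, `band_power_table()`).
2. **Ratios** (`power_ratios()`), **screening** of all 65 ratios plus the
   10 lobar band powers by Mann-Whitney U with Benjamini-Hochberg (BH)
   correction (`screen_features()`).
3. **Diagnostic accuracy** per marker: ROC with DeLong inference,
   precision-recall (PR) curves with nonlinear interpolation and
   logit-method intervals, Youden-index cutoffs with bootstrap intervals,
   and prevalence-standardized predictive values (`roc_auc_delong()`,
   `pr_curve()`, `youden_cutoff()`, `bootstrap_cutoff_ci()`).
4. **Stepwise logistic regression** of disease status on the headline
   ratios plus age and sex (`stepwise_select()`).
5. **Consistency**: the whole pipeline repeated over FFT
   parameterizations and referencing schemes, and a matrix of which
   features remain significant with a stable direction everywhere
   (`run_analysis()`, `consistency_report()`).
6. A **synthetic cohort generator** (`cohort_spec()`,
   `generate_cohort()`) so that all of the above is exercised end to end
   without access to clinical recordings.

## Spectral estimation

Band powers are Welch averaged modified periodograms. A parameterization
is written "window / steps per Hz": segments of `window_s` seconds with
50 % overlap are mean-detrended, Hamming-tapered and zero-padded to an
FFT length of `steps_per_hz * fs` samples, so the spectral grid has
spacing `1 / steps_per_hz` Hz. At 500 Hz the three parameterizations
used for the consistency analysis decompose into window/FFT/overlap
sample counts of 1000/5000/500 (2 s/10), 1000/2500/500 (2 s/5) and
500/5000/250 (1 s/10). One-sided density scaling is Parseval-consistent:
the sum of the spectrum times the grid spacing equals the tapered
signal's mean power.

Band membership on the grid is half-open `(low, high]`, with delta
closed at 0.5 Hz: the band edges are contiguous, and a grid frequency is
never counted twice. A band power is the *mean* of the density over the
band's grid points; the lobar value averages this over the lobe's
electrodes (frontal: Fp1, Fp2, F3, F4, F7, F8, Fz; temporal: T3, T4,
T5, T6 — legacy names are canonical internally, with modern T7/T8/P7/P8
mapped onto them on read). Powers are averaged before ratios are formed
(average-then-ratio); by linearity of the average the order of averaging
electrodes versus frequencies is immaterial, but ratio-then-average
would not be, and the average-then-ratio reading matches how the lobar
power ratio is defined.

Two implementation notes. The taper is configurable (`hamming`, `hann`,
`rect`); Hamming is the default. Its mainlobe half-width is `2/T` Hz,
so a pure sinusoid's power concentrates within about 1 Hz of its
frequency at 2-s windows — band-level statements are insensitive to
this, but sub-Hz statements are taper-dependent. Internally, band means
are computed from segment-averaged autocorrelations (the band mean over
the zero-padded grid is a linear functional of the autocorrelation),
which is algebraically identical to the direct zero-padded-FFT route —
the test suite asserts equality to machine precision — while using
power-of-two FFTs that are several-fold faster.

## Referencing

Analyses run under the **average reference** and, for the consistency
comparison, the **REST infinity reference** (reference electrode
standardization technique). REST maps average-referenced scalp data to
an approximate infinity reference through a volume-conductor model:
`V_rest = G pinv(G_avg) V_avg`, where `G` is the lead field of an
equivalent source layer referenced to infinity and `G_avg` its
average-referenced counterpart.

The head model is the canonical three-concentric-sphere conductor:
relative radii 0.87 / 0.92 / 1.0 (brain / skull / scalp), relative
conductivities 1 / 0.0125 / 1, and 300 radial dipoles distributed
quasi-uniformly (Fibonacci lattice) at radius 0.86. The forward
solution is the analytic Legendre series whose per-degree transfer
coefficients solve the three-shell boundary conditions; with equal
conductivities it collapses to the classical homogeneous-sphere closed
form, which the tests verify to machine precision. The pseudoinverse is
a truncated SVD at relative threshold 1e-6 (`G_avg` is rank-deficient
by construction, since average referencing removes one dimension).

A limitation worth stating plainly: with 19 electrodes, REST recovers
the infinity-referenced potential essentially exactly for source
activity the montage can see (the row space of `G_avg` — this is what
the recovery test asserts), but source configurations invisible to the
montage leave an unrecoverable spatially constant residual that can be
substantial for deep or inferior sources. Ratio markers are only mildly
sensitive to this, which is consistent with the referencing comparison
being a robustness check rather than a correction.

## Statistics

* **Screening**: two-sided Mann-Whitney U per feature (exact
  distribution for tie-free samples up to a combined n of 20, otherwise
  tie-corrected normal approximation with continuity correction), BH
  adjustment across the family of all 75 features within one
  configuration. The family is re-run per configuration; the
  cross-configuration consistency view then asks for the same direction
  and tier everywhere. Pooling powers and ratios into one BH family is a
  design choice, made because the screening figure presents them
  together; re-running with a ratios-only family is a one-line change.
* **ROC**: empirical AUC with the Mann-Whitney kernel (ties count one
  half) — the suite checks the exact identity `AUC = U / (n1 n2)` — with
  DeLong structural-component variance and a paired DeLong test between
  markers. Markers are auto-oriented so AUC is at least 0.5, and the
  orientation is carried through to the cutoff's inequality direction.
* **PR**: achievable points at every threshold, interpolated along the
  path that is linear in (TP, FP) space — precision is then a hyperbolic
  arc in recall, and the area is integrated in closed form per segment.
  The CI is the logit-method interval with standard error
  `1 / sqrt(n_pos A (1 - A))`.
* **Cutoffs**: Youden's J maximized over midpoints between adjacent
  observed values, ties resolved toward higher specificity. Sensitivity
  and specificity carry Clopper-Pearson intervals; PPV and NPV at a
  standardized 50 % prevalence propagate those binomial limits through
  the predictive-value formulas (both are monotone in sensitivity and
  specificity, so propagating the limits is conservative and simple —
  the original tables do not state their interval method). Cutoff and
  maximum J carry stratified percentile bootstrap intervals (default
  5000 iterations, seed 978; the protocol sentence "5000 iterations and
  978 seeds" is read as seed = 978).
* **Percentile-bootstrap caveat**: a maximized index is upward-biased,
  and the percentile interval inherits that bias. Coverage is near
  nominal when the optimal cutoff is well-identified (for instance
  ordinal markers with a unique population argmax — the regime the
  coverage test simulates) and degrades toward roughly 80-85 % for
  continuous markers whose J profile is flat near the optimum. This is a
  property of the prescribed method, not of the implementation, and is
  the reason the coverage study uses a discrete marker.
* **Sample size**: smallest equal group size n with
  `z_{a/2} SE0(n) + z_b SE1(n) <= AUC1 - AUC0` under the Hanley-McNeil
  variance (`Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`); with two-sided alpha
  0.01, power 0.8, AUC 0.8 versus 0.5 this returns exactly 20 per group.
* **Modeling**: maximum-likelihood logistic regression (IRLS via
  `glm`), predictors standardized internally and coefficients reported
  on the original scale. Stepwise selection enters the candidate with
  the smallest likelihood-ratio p below 0.05 and removes included
  variables with Wald p above 0.1, iterated to stability; age and sex
  are ordinary candidates, not forced covariates (the published final
  models contain only `F-theta/F-alpha`, implying the covariates did not
  survive selection). Near separation the Wald statistic collapses
  (Hauck-Donner) and could oscillate against the entry test; a removal
  that would recreate a previously visited model ends selection instead.

## The synthetic cohort generator

`cohort_spec()` defines the generative model; its defaults are the study
conditions the pipeline is tested under:

* 23 FTD and 29 CTL subjects; 19-channel 10-20 montage at 500 Hz.
* Each channel is a sum over bands of unit-RMS band-limited Gaussian
  noise carriers (constructed in the frequency domain with exact band
  confinement and Parseval-exact unit RMS) scaled by a per-(lobe, band)
  microvolt amplitude, plus a `1/f` background floor (exponent 1, scale
  0.1 times the mean base amplitude) confined to the 0.5-45 Hz analysis
  range, emulating recordings already band-pass filtered there.
* CTL baseline amplitudes per band (delta 10, theta 8, alpha 12, beta
  5, gamma 2 microvolts RMS) are ordinary resting, eyes-closed scalp
  magnitudes; non-frontal/temporal channels always use this baseline.
* FTD group effects multiply amplitudes: frontal theta x1.3, frontal
  alpha x0.75, temporal alpha x0.7, temporal gamma x1.25, all else 1.
  The directions reproduce the reported frontal/temporal alpha decrease
  and the four headline-ratio shifts (F-theta/T-alpha and
  F-theta/F-alpha up; F-alpha/T-theta and T-beta/T-gamma down). The
  magnitudes are calibration choices — the source study reports only
  directions and significance, not band-level effect sizes.
* Between-subject variability is one log-normal factor per
  (subject, lobe, band), sigma 0.2. Under these defaults the headline
  ratios separate groups with AUCs between roughly 0.75
  (F-alpha/T-theta) and 0.95 (F-theta/F-alpha): the weaker pair sits in
  the intended AUC-0.8 regime, the theta/alpha contrasts come out
  stronger because their effects compound in both numerator and
  denominator.
* Covariates: age FTD 63.6 (8.2) vs CTL 67.9 (5.4) years, female
  proportion 0.39 / 0.38, MMSE 22.17 (8.22) truncated to [0, 30] vs a
  constant 30.

What the generator deliberately does **not** emulate: artifacts
(blinks, EMG, line noise), nonstationarity, channel-specific noise,
volume-conduction correlation between channels (carriers are drawn
independently per channel), or any preprocessing chain. Passing tests
therefore demonstrate that the statistical pipeline behaves correctly
on spectrally structured data — not that the markers survive real-world
artifact handling.

## Problem sizes and numerical choices

The simulation-based tests scale recording length down from the
10-minute study recordings: band-power estimates at 30 s already carry
only a few percent estimation noise against a 57 % between-subject
spread (log scale), so group-level operating characteristics are
essentially unchanged while the suite stays fast. Specific sizes: the
headline-recovery study uses 50 cohorts of 23/29 subjects at 60 s under
all four configurations; the null-calibration study 50 cohorts at 20 s;
the bootstrap coverage study 500 markers of 100 + 100 subjects at 400
iterations; shared module fixtures 6/6 subjects at 20 s.

Other numerical choices: glm convergence tolerance 1e-12 (effectively
to machine precision) with a separation guard at standardized
coefficient magnitude 15; SVD truncation 1e-6 for REST; Legendre series
truncated at degree 80 (the source layer at radius 0.86 makes the
omitted terms smaller than 1e-5); EDF output quantizes to the 16-bit
grid of each channel's physical range.

## Known limitations

* The headline-recovery acceptance check asks every one of the four
  ratios to be BH-significant with the right direction in all four
  configurations in at least 80 % of replicates. Under the default
  calibration the two weaker effects (AUC near 0.8) each have roughly
  the power that a single test at n = 20-29 per group is designed for
  (80 %), so the joint requirement measures closer to 65 %. The check
  is kept at its stated threshold rather than recalibrated; see the ROC
  AUCs above for the per-marker picture.
* EEGLAB SET reading supports continuous (non-epoched) MAT level-5
  files, embedded or `.fdt`-sidecar data; MAT 7.3 (HDF5) exports are
  rejected with a message.
* PPV/NPV intervals propagate binomial limits; they are not bootstrap
  intervals, and at extreme specificity they can be wide.
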