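---
title: "Phase congruency binary patterns: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase congruency binary patterns: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the method it implements: what
is computed, why each tunable is set the way it is, what the synthetic
phantoms do and do not emulate, and where genuinely open design choices were
resolved.

## The problem

Breast-ultrasound (BUS) computer-aided diagnosis classifies a manually
cropped tumor region of interest (ROI) as benign or malignant. Sonographic
morphology separates the classes: benign masses tend to be elliptical with
smooth, well-defined borders and homogeneous internal echoes; malignant
masses tend to be irregular, with blurred, angular ("spiculated") borders
and heterogeneous interiors. Texture descriptors that read this structure
directly from gray levels are fragile: ultrasound scanners remap intensity
freely (gain, dynamic range, post-processing), so a descriptor trained on
one contrast setting can degrade on another.

The descriptor implemented here — *phase congruency binary patterns*
(PCBP) — addresses that fragility by encoding structure in the *phase* of
the local frequency decomposition rather than in raw intensity.

## Oriented phase congruency

Phase congruency (PC) marks points where the local Fourier components
arrive in phase — step edges and ridges — and is invariant to the overall
signal magnitude. Per orientation $o$ the implementation computes, at every
pixel,

$$
PC_o = \frac{W_o \,\big\lfloor \sum_s A_{s,o}\,\Delta\phi_{s,o} - T_o \big\rfloor}
            {\sum_s A_{s,o} + \varepsilon},
$$

where $A_{s,o}$ and $\phi_{s,o}$ are the amplitude and phase of the
response of a log-Gabor quadrature pair at scale $s$,
$\Delta\phi = \cos(\phi - \bar\phi) - |\sin(\phi - \bar\phi)|$ penalizes
deviation from the amplitude-weighted mean phase $\bar\phi_o$, $W_o$ is a
sigmoid weight favouring responses spread over many scales,
$\lfloor\cdot\rfloor$ zeroes negatives, $T_o$ is a noise floor and
$\varepsilon$ guards the denominator. $PC_o \in [0,1]$ by construction:
the numerator is bounded by the denominator term by term.

The energy term $A\,\Delta\phi$ is evaluated in dot/cross-product form
against the unit mean-phase vector (`e*cos + o*sin - |e*sin - o*cos|`),
which is algebraically identical to the trigonometric form but stable when
$A \approx 0$ — no arctangents are taken.

### Filter bank

Log-Gabor filters have a Gaussian transfer function on the log-frequency
axis, hence strictly zero DC response, and are applied in the frequency
domain with periodic boundary handling at the image's native size (no
padding). Defaults, exposed in `log_gabor_bank()` / `pcbp_params()`:

| parameter        | default | meaning |
|------------------|---------|---------|
| `scales` (S)     | 6       | wavelet scales |
| `orientations` (O)| 8      | angular channels spanning a half-turn |
| `lambda_min`     | 3 px    | smallest-scale wavelength |
| `mult`           | 2.1     | wavelength ratio between scales |
| `sigma_onf`      | 0.55    | radial log-Gaussian bandwidth ratio (~2 octaves) |
| `theta_spread`   | 1.2     | orientation spacing / angular sigma |
| `cutoff`, `gain` | 0.4, 10 | spread-sigmoid parameters of $W_o$ |
| `eta`, `epsilon` | 1e-4    | division guards |
| `k_noise`        | 2       | noise floor strength; 0 disables |

S, O, the sigmoid constants and the guards follow the published
configuration of the method; the filter-geometry values are the reference
defaults of the underlying PC implementation, since the published
description does not state them. Printed PC images therefore cannot be
matched bit-exactly, only structurally.

### Input normalization and gray-scale invariance

Images are min-max normalized to $[0,1]$ before filtering. This fixes the
scale that `eta`, `epsilon` and $T_o$ operate on and makes the whole
pipeline *exactly* invariant under any affine intensity map $aI+b$
($a>0$) — including the contrast-improvement transform — regardless of the
noise-compensation setting. With `k_noise = 0` the computation is the
purely contrast-invariant regime used by the invariance tests (agreement
to 1e-6; the residual is floating-point noise, since $\eta,\varepsilon$
act on an identical normalized input).

### Noise compensation

The published description delegates the estimation of $T_o$ to its
reference implementation, so this package follows that recipe: the
amplitude of the smallest-scale filter on noise is Rayleigh distributed, so
its median estimates the noise sigma (`median / sqrt(log 4)`); the sigma is
extrapolated across scales by the bandwidth ratio and converted to the mean
and standard deviation of the implied total noise energy;
$T_o = \text{mean} + k_{noise}\,\text{sd}$ is subtracted from the
*total* scale-summed energy before zeroing. We considered subtracting a
per-scale share of $T_o$ inside the sum instead; on pure white noise that
variant leaves roughly half the pixels above threshold at $k_{noise}=2$,
whereas total-energy subtraction silences more than 98% of them, which is
the behaviour the method is meant to have.

A consequence worth stating plainly: because the floor is estimated from
the data, it *adapts* to gray-scale transforms. On the synthetic phantoms
this matters more than it would clinically, since benign phantom interiors
are by construction pure speckle — exactly the component the noise floor
removes — so their entire texture signal sits at the threshold boundary. A
nonlinear gray map (gamma, equalization) rescales speckle contrast
relative to the adaptive threshold and can move benign interiors above it,
making them resemble malignant heterogeneity; in the bundled study this
inverts the class ranking under gamma correction at $k_{noise}=2$. The
gray-scale robustness protocol is therefore evaluated in the
contrast-invariant regime ($k_{noise}=0$), where the phase-congruency
invariance theory applies and the cross-contrast AUCs agree to within a
few thousandths; the plain class-separation study keeps the full default
descriptor ($k_{noise}=2$). Both regimes are exercised by the test suite.

## Local binary patterns on PC maps

Each oriented PC map is encoded with rotation-invariant uniform local
binary patterns: neighbor $p$ of $P$ sits at angle $2\pi p/P$ on the circle
of radius $R$; off-grid samples are bilinearly interpolated; the sign
convention is $s(x)=1$ for $x \ge 0$ (ties count as "not below center").
A pattern with at most two circular 0/1 transitions maps to its count of
set bits, all others to the non-uniform bucket $P+1$, giving $P+2$ codes
(10 for $P=8$). Each pixel contributes its neighborhood's population
variance — the local contrast — to its code's bin (the LBPV weighting),
and the $P+2$-bin histogram of each orientation is L1-normalized before the
$O$ blocks are concatenated: $(P+2)\times O = 80$ features under defaults.

Design notes, where the published description is silent:

* **Interpolation.** Bilinear, the standard choice in the LBP literature.
  A consequence worth knowing: interpolation is linear, so riu2 codes
  commute exactly with *affine* intensity maps but not with arbitrary
  monotone ones — a nonlinear map can flip comparisons whose interpolated
  neighbor sits very close to the center value. On smooth real maps the
  effect is marginal; the tests quantify it on worst-case uniform noise.
* **Borders.** Only pixels with a complete circular neighborhood
  contribute (`valid_mask`); no padding, so no fabricated texture at ROI
  edges.
* **Normalization.** Per-orientation L1 rather than global, so each
  orientation block carries comparable mass; degenerate all-zero blocks
  (constant maps) are left at zero rather than renormalized.
* **Uniformity formula.** The printed transition count contains an
  obviously degenerate summand (a difference of a term with itself); the
  implementation uses the standard circular transition count the
  surrounding text describes.

The plain-LBP comparison descriptor (`compute_lbp_baseline()`) applies the
same riu2 coding directly to the raw gray image with $P=24$, $R=3$ and
*count* weighting (26 features) — it is a comparator, deliberately not
variance-weighted and not PC-based.

## Classification protocol

An RBF-kernel SVM separates the classes (malignant = positive throughout).

* **Scaling.** Every feature is affinely mapped so the *training* minimum
  and maximum hit $-1$ and $+1$; test values may fall outside (no
  clipping); constant training columns map to 0 (the symmetric choice).
  Scaling is refitted inside every resampling loop so no test information
  leaks into the scaler.
* **Grid search.** $C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$ in steps of
  $2^2$ (a finer $2^1$ grid is available via `svm_grid(step = 1)`),
  selected by stratified 10-fold cross-validated accuracy with a fixed
  fold seed; ties break toward smaller $C$, then smaller $\gamma$. The
  selected pair is then *fixed* for the evaluation protocols, mirroring
  the practice of selecting once on the training database; nested
  re-selection inside each LOO round is possible by calling
  `grid_search_svm()` per fold but is not the default. Caveat: on small
  perfectly separable datasets large parts of the CV-accuracy surface tie
  at 100%, and the tie rule then selects the most-regularized corner of
  the grid — a near-zero-margin model whose leave-one-out behaviour is
  dominated by the one-case class imbalance of each round. Inspect the
  `cv_accuracy` attribute, or set `svm_config()` by hand, when the
  accuracy surface is flat.
* **LOO-CV.** $n$ rounds, one held-out decision value each; the report
  pools the scores (AUC via trapezoidal ROC — decision values, not hard
  labels, since labels alone cannot produce a smooth ROC) and thresholds
  at 0 for the confusion-matrix metrics.
* **Bootstrap.** 500 replicates; each resamples $n$ cases with
  replacement for training and tests on the out-of-bag remainder
  (~36.8%). Replicates whose training or OOB set lacks a class are redrawn
  and counted (`$redraws`); at $n=120$-plus this is vanishingly rare.
* **Metrics.** ACC, SENS, SPEC, PPV, NPV, MCC evaluated exactly from the
  confusion matrix; any zero denominator yields `NA`, never a silent 0.
* **Cross-contrast scheme.** The scaler and SVM are fitted only on
  original-image features; round $i$ of LOO scores the gray-scale
  transformed copy of held-out case $i$. The identity transform reproduces
  the ordinary LOO report exactly.

## Gray-scale transforms

Three monotone families probe robustness: contrast improvement (affine
range map, default full $[0,1]$), gamma correction ($x^\gamma$, default
$\gamma = 0.5$), and histogram equalization (CDF remap, 256 bins). The
published experiments do not state their exact parameterizations, so these
defaults are representative members of each family, all exposed in
`transform_spec()`. Because the power law acts on the display range
$[0,1]$ and has no black-level shift, the gamma transform clips float
inputs whose values stray outside (speckle highlights), exactly as 8-bit
storage would saturate them; it deliberately does *not* subtract the
minimum, which would push hypoechoic interiors into the near-zero region
where $x^{\gamma}$ amplifies speckle contrast without bound.

## Synthetic phantoms

The clinical 138-case database behind the published results is not
deposited, so the package ships a deterministic generator of BUS-like
speckle phantoms that makes every stage testable end to end:

* geometry: a centered ellipse (random axes 0.26–0.34 of each dimension,
  random orientation); malignant radii are additionally modulated by three
  sinusoidal lobes of angular frequency 3–8 and total relative amplitude
  0.25 ("spiculation");
* echogenicity: hypoechoic interior 0.32 against background 0.62, border
  blurred with $\sigma$ = 1.5 px (benign) or 4 px (malignant); malignant
  interiors add a smooth heterogeneity field (amplitude 0.15, correlation
  8 px);
* speckle: multiplicative correlated Rayleigh noise with analytic unit
  mean (magnitude of a smoothed complex Gaussian field), correlation
  length 1.5 px;
* sizes sampled uniformly in the ROI range 82–330 × 104–473 px; every
  image is a pure function of its seed, and dataset-level seeds derive
  deterministically from one master seed.

These phantoms emulate the *class-conditional texture contrast* the
descriptor exploits — organized boundary energy for benign masses,
dispersed in-phase points for malignant ones — but not ultrasound physics:
no point-spread anisotropy, attenuation, shadowing, or time-gain artifacts,
and the echogenicity defaults are not validated against clinical ROIs. A
high phantom AUC therefore demonstrates that the pipeline detects the
morphology it encodes, not clinical-grade performance.

## Study sizes and numerical choices

The bundled evaluation study uses 60 benign + 60 malignant phantoms with
LOO-CV and the cross-contrast scheme, and a 100-case label-permutation
null; these sizes give stable AUC estimates for a desk-scale study while
keeping the full suite fast. Other numerics: FFT filtering at native image
size (periodic boundaries, matched by the direct-convolution test oracle);
neighbor offsets within 1e-9 of an integer are snapped before
interpolation; variance accumulations are clamped at 0 against negative
floating-point round-off; ROC ties count one half (verified against an
$O(n^2)$ concordance oracle).

## Known limitations

* PC images cannot be reproduced bit-exactly against published figures
  (unstated filter geometry).
* The adaptive noise floor makes maps and descriptors only approximately
  stable under nonlinear gray-scale transforms; on phantoms whose benign
  texture is pure speckle this can invert the class signal, so robustness
  claims hold in the contrast-invariant regime (`k_noise = 0`) and should
  be re-validated per dataset when compensation is on.
* riu2 codes are exactly invariant to affine, not arbitrary monotone,
  intensity maps (interpolation, above).
* Phantom realism is morphological, not acoustic.
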