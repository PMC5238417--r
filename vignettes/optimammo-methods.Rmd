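---
title: "Methods: perturbative time-domain optical mammography analysis"
author: "optimammo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbative time-domain optical mammography analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the model

A scanning optical mammograph injects picosecond laser pulses at seven
red/near-infrared wavelengths (635–1060 nm) into the mildly compressed
breast and histograms the photons transmitted along the line of sight with
time-correlated single-photon counting, storing one curve per millimeter of
scan path. `optimammo` implements the full analysis chain for such data:

1. **Forward model.** Light propagation is described by the diffusion
   approximation for a homogeneous slab with extrapolated boundary
   conditions. `slab_transmittance()` evaluates the image-source (dipole)
   series for the time-resolved transmitted flux; the series is truncated at
   `m_max = 10` dipole pairs, whose contribution decays super-exponentially,
   and the time integral agrees with the independent continuous-wave closed
   form to better than 0.1%.
2. **Perturbation model.** A lesion is treated as a spherical absorbing
   inhomogeneity of known equivalent diameter, placed halfway between source
   and detector. The measured and reference curves are linked by the
   time-resolved modified Beer–Lambert law
   `T(t) = T0(t) exp(-delta_mua * l(t))`, where `l(t)` is the mean pathlength
   traveled inside the sphere by photons detected at time `t`.
   `partial_pathlength()` computes `l(t)` as a first-order Born sensitivity:
   the time convolution of the source-to-voxel fluence and voxel-to-detector
   transmittance Green's functions, integrated over the sphere by
   Gauss–Legendre quadrature (default 16 nodes per spherical coordinate,
   configurable; the phantom workflows use 8 per coordinate, which agrees
   with the 16-node result to well below the photon noise of the studies
   shipped here). Higher-order perturbation schemes exist in the literature,
   but their coefficients are not reproducible from generally available
   sources; the first-order kernel is validated directly against the
   package's Monte-Carlo photon-transport oracle (agreement within 15% for
   late photons in the diffusive regime, and within 5% for gated
   transmittance ratios at `delta_mua * max(l) <= 0.2`).
3. **Time gating.** Curves are divided into 10 equal-count windows and the
   8th window — late, absorption-sensitive photons that are least affected
   by scattering changes — carries the contrast estimate.
4. **Spectral unmixing.** The Beer law `delta_mua(lambda) = sum_i
   eps_i(lambda) delta_C_i` converts 7-wavelength absorption differences
   into concentration differences of oxy- and deoxyhemoglobin, water, lipid
   and collagen by unconstrained linear least squares (`unmix()`); the
   differences are signed, so no non-negativity is imposed (a Lawson–Hanson
   non-negative mode exists for absolute compositions).
5. **Statistics and classification.** Group comparisons use multivariate
   permutation tests on means and variance–covariance matrices, Euclidean
   distance profiles with a Mann–Whitney test, and Pearson correlations;
   lesion discrimination uses Discrete AdaBoost over depth-limited Gini
   trees with per-round bagging, repeated held-out evaluation, and
   impurity-based variable importance.

## Key parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| slab thickness | 4 cm | mildly compressed breast; configuration parameter of `slab_geometry()` |
| refractive index | 1.4 | soft tissue; sets `v = c/n` and the extrapolated distance through the internal-reflection coefficient |
| `m_max` | 10 | dipole pairs in the image series |
| windows `K` | 10 | equal-count gates; window 8 is analyzed |
| IRF FWHM | 600 ps (presets) | detection-chain blur, 460–930 ps across wavelengths for this instrument class |
| fit range | 80% rising – 1% tail | homogeneous-fit window on the peak-normalized curve |
| ROI side | 5 mm (diameter <= 15 mm), 9 mm (> 15 mm) | lesion-area rule, read with a strict inequality at 15 mm |
| reference region | mask eroded 10 mm, 3-MAD window-8 trim | "most of the breast, excluding boundaries and marked inhomogeneities"; both parameters configurable, and the phantom studies use 3–4 mm erosion because their grids are only a few centimeters wide |
| boosting | M = 50, depth-2 trees, bagging | customary tree-boosting defaults; coefficients `c_m = log((1-err)/err)` without the 1/2 factor |

## Numerical choices

* **Equal-count windows.** A greedy partition at whole-bin boundaries cannot
  hold each window to `total/K` counts when single bins are large, so window
  totals are computed by splitting the boundary bin proportionally (photon
  arrivals are uniform within a bin); the greedy bin-index boundaries are
  reported alongside. Gate boundaries always come from the reference curve
  and are applied unchanged to the lesion curve — regating each curve
  separately would cancel the very contrast being measured.
* **Window-level inversion.** Applying the per-bin Beer–Lambert factor and
  then summing a window is not exactly invertible by the scalar
  `log(T0/T)/l̄` formula; `estimate_delta_mua()` therefore solves
  `sum(T0(t) exp(-delta_mua l(t))) = T_w` by bracketed 1-D root finding when
  given the per-bin kernel, which undoes a per-bin perturbation to solver
  precision. The scalar closed form (count-weighted `l̄`) is retained and is
  accurate to first order.
* **Instrument response.** Fitting is convolution-forward (the model is
  convolved with the IRF, never the data deconvolved), with Poisson weights
  `1/max(counts, 1)`, analytically profiled amplitude, and Nelder–Mead on
  `log(mua), log(musp)`. For gating-based contrast estimation the kernel is
  moved to the measured time axis as
  `l_eff = conv(T0 l, irf) / conv(T0, irf)`; `quantify_lesion()` goes one
  step further and models the gated ROI-mean attenuation with the exact
  perturb-then-convolve chain, per lateral offset of each ROI pixel from the
  lesion center.
* **Degenerate inputs.** Curves that are essentially the bare IRF drive the
  homogeneous fit to implausible scattering values and are flagged rather
  than returned silently; spheres touching a slab face, empty reference
  regions, rank-deficient extinction tables and single-class cohorts are
  rejected with errors.
* **Tie-breaks.** Tree splits use midpoint thresholds with ties in impurity
  gain broken to the lowest variable index and lowest threshold; leaf votes
  tie to the benign class, as does a zero ensemble score (flagged).
* **Boosting edge cases.** A perfect round (`err = 0`) receives a large
  finite capped coefficient and the loop continues; a round with
  `err >= 0.5` is discarded and redrawn under bagging (without bagging the
  ensemble is truncated at that round with a warning).

## The synthetic-data module

No patient data are distributed with the package, so `synthetic_data`
generates every input the pipeline consumes, with the statistical structure
the clinical study reports:

* **Cohorts** (`generate_cohort()`): 45 malignant and 39 benign lesions
  whose five composition-difference features are Gaussian with *equal means*
  but *different covariances* — the malignant group inflates the HbO2 and
  collagen variances threefold and carries a weak negative collagen–lipid
  correlation (−0.271) against an essentially null benign one (−0.079) —
  plus healthy-background collagen and lipid contents correlated at −0.78,
  and anamnesis covariates (age and BMI truncated normal on 40–75 years and
  18–35 kg/m², parity 0–4, familiarity and oral-contraceptive Bernoulli,
  Tamoxifen at 3/84). Printed coefficients used here are generator
  *anchors*, not reproduced findings. Feature standard deviations are of one
  common order of magnitude, matching the reported comparability of the
  interquartile ranges. Group means and feature scales beyond those anchors
  are plausible choices, fixed once.
* **Phantoms** (`generate_phantom_scan()`): a homogeneous slab whose
  background absorption derives from a plausible absolute composition via
  the packaged extinction table (with a `(lambda/800)^-1` scattering law),
  scanned at 1 mm pitch, with an embedded sphere whose composition
  difference is converted to per-wavelength `delta_mua` through the *same*
  extinction table used for unmixing — the generation/analysis loop is
  exactly consistent by construction. Curves are IRF-convolved and
  Poisson-sampled; the planted truth is returned as a sidecar. The
  `carcinoma-phantom` preset (18 mm lesion, 9×9 ROI) is the reference
  end-to-end scenario at 10^6 counts per pixel; `fibroadenoma-phantom`
  (10 mm, 5×5 ROI) exercises the small-lesion rule, where window-8 photon
  noise through the near-collinear lipid/collagen spectra dominates the
  recovery error.
* **Bayes-calibrated cohort** (`bayes15-cohort`): two equal-covariance
  Gaussians (200 + 200 lesions) separated along the collagen axis by twice
  `qnorm(0.85)` standard deviations, so the optimal rule errs at exactly
  15%; the held-out boosting error is validated against this analytic
  anchor.

What the generator deliberately does **not** emulate: anatomical
heterogeneity (vessels, glandular structure) beyond outlier pixels,
scattering perturbations (lesions are absorption-only, as in the perturbative
model itself), inter-wavelength co-registration errors, detector afterpulsing
and background. Passing tests therefore demonstrate the correctness and
calibration of the *pipeline*, not clinical performance: the study's
clinical accuracy figures depend on an undeposited 84-patient cohort and are
out of reach by design.

## Extinction table provenance

The packaged table (`extinction_defaults_synthetic.csv`) is a synthetic,
literature-shaped set of extinction coefficients: hemoglobin dominance below
800 nm, the lipid peak near 930 nm, the water peak near 975 nm, and collagen
sensitivity concentrated at 685 and 1060 nm. It is *not* a measured
reference (the constituent spectra used clinically are lab-measured and not
printed in public sources), so absolute concentration differences obtained
with it are illustrative; every quantitative test in the package is a
round trip through the same table. Its condition number (~300) is reported
at load time because it controls the noise amplification of the unmixing
step, particularly between the partially collinear lipid and collagen
columns.

## Problem sizes used by the validation studies

The shipped studies are sized for a single CPU: Monte-Carlo comparisons use
1.5–4 million photons; the end-to-end phantom is a 45×45 mm scan at 10^6
counts per pixel; calibration uses 1000 null datasets at 99 permutations and
power 200 cohorts at 199 permutations; boosting calibration uses 20 repeats
of 50 rounds on 400 lesions. These sizes keep every Monte-Carlo standard
error several times smaller than the tolerance it is compared against.

## Known limitations

* The Born kernel is first order in `delta_mua`; strong absorbers
  (`delta_mua * l` well above ~0.5 in the analysis window) are increasingly
  underestimated.
* The homogeneous-background assumption biases maps near the breast edge;
  the mask erosion mitigates but does not remove this.
* Collagen is modelled as a single constituent; additional collagen types
  or elastin would require extending the extinction table.
* The covariance-comparison statistic (Frobenius norm of the difference of
  group covariance matrices) and the mean statistic (squared norm of the
  mean difference) are reasonable defaults for the named tests; Mahalanobis
  and distance-matrix variants would be straightforward alternatives behind
  the same permutation engine.
* The evaluation protocol is repeated random holdout (a third of the cohort
  per run). An out-of-bag mode exists but is diagnostics-only: with
  weight-proportional bagging, the rounds for which a frequently
  misclassified point is out-of-bag are exactly the rounds that had not yet
  adapted to it, and the resulting estimate is pessimistic by roughly a
  factor of two on the Bayes-calibrated preset. Resubstitution is
  deliberately not offered as a headline metric.
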