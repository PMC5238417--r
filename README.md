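# optimammo

Analysis pipeline for **time-domain diffuse optical mammography**: from
picosecond photon-counting transmittance curves through a compressed breast
to lesion composition contrast and malignant-vs-benign classification.

Breast lesions differ from the surrounding tissue in blood, water, lipid and
— notably, through desmoplasia — collagen content. A scanning optical
mammograph measures time-resolved transmittance at seven wavelengths
(635–1060 nm); because the lesion is a localized absorption perturbation
in an otherwise homogeneous slab, the measured curve `T(t)` and the
healthy-tissue reference `T0(t)` are linked by the time-resolved modified
Beer–Lambert law

    T(t) = T0(t) · exp(−Δμa · l(t))

where `l(t)` is the mean pathlength traveled inside the lesion by photons
detected at time `t` (computed here as a first-order Born sensitivity for an
equivalent sphere) and `Δμa` the lesion–background absorption difference.
Gating the curves into 10 equal-count windows and inverting window 8 (late,
absorption-sensitive photons) gives `Δμa` at each wavelength; the Beer law

    Δμa(λ) = Σ_i ε_i(λ) · ΔC_i

then unmixes the spectra into concentration differences of Hb, HbO2, water,
lipid and collagen. Cohorts of such lesion fingerprints are compared with
multivariate permutation tests (means and variance–covariance matrices) and
classified with Discrete AdaBoost over decision trees, with impurity-based
variable importance.

The package is aimed at physicists and biostatisticians working with
time-domain diffuse optics. No patient data ship with it: a first-class
synthetic module generates slab-phantom scans with planted spherical lesions
and two-group cohorts that reproduce the qualitative clinical signature
(equal mean vectors, different covariance structure, a strong negative
background collagen–lipid correlation), and a compiled Monte-Carlo photon
transport oracle validates the diffusion forward model.

## Worked example

```r
library(optimammo)

## a 45 x 45 mm phantom scan with an 18 mm carcinoma-like lesion
spec <- preset_catalog()[["carcinoma-phantom"]]
ph   <- generate_phantom_scan(spec, seed = 1)
scan <- ph$scan

mask <- breast_mask(scan, count_threshold = 1e5)
ref  <- reference_curve(scan, mask, erosion_mm = 4)
irf  <- gaussian_irf(scan$time_ps, spec$irf_fwhm_ps)

les <- quantify_lesion(scan, ref, ph$truth$center_mm, ph$truth$diameter_mm,
                       spec$props_list, slab_geometry(spec$thickness_cm),
                       spec$spectra, nq = c(8, 8, 8), irf = irf)
round(rbind(truth = ph$truth$delta_c, estimate = les$delta_c[1:5]), 1)
#>          Hb HbO2 water lipid collagen
#> truth     8 15.0  60.0 -40.0     45.0
#> estimate  8 14.9  59.7 -37.5     47.5
```

The estimate row is the window-8 inversion of the scanned curves through the
equivalent-sphere pathlength kernel, unmixed with the packaged extinction
table: the planted composition difference (in µM for the hemoglobins,
mg/cm³ otherwise) is recovered within a few percent at 10⁶ counts per
pixel.

```r
## the clinical statistical signature on a synthetic cohort
co <- generate_cohort(cohort_spec(), seed = 1)       # 45 malignant / 39 benign
f  <- cohort_features(co, "composition")
permutation_mean_test(f$X, f$y, n_perm = 9999, seed = 2)$p_value
#> [1] 0.7362     # the group means do not differ, by construction
covariance_permutation_test(f$X, f$y, n_perm = 9999, seed = 3)$p_value
#> [1] 0.1845     # one of the quieter draws: across repeated cohorts of this
#>                # size the covariance test rejects at the 5% level in over
#>                # 80% of datasets (scripts/acceptance.R measures this power)

## Discrete AdaBoost on the Bayes-calibrated benchmark cohort
pb <- preset_catalog()[["bayes15-cohort"]]     # analytic Bayes error 15%
cb <- generate_cohort(pb, seed = 5)
fb <- cohort_features(cb, "composition")
evaluate_repeated(fb$X, fb$y, runs = 20, M = 50, seed = 6)
#> Discrete AdaBoost evaluation (20 runs of 50 rounds, holdout):
#>   misclassification   19.0 +/- 1.9 %
#>   sensitivity         80.6 +/- 4.5 %
#>   specificity         81.6 +/- 4.2 %
#>   AUC = 0.881
#>   importance rank: dCollagen > dHbO2 > dHb > dWater > dLipid
```

The held-out misclassification sits a few points above the 15% optimum, as
expected for trees fitted to 400 lesions.

A command-line wrapper for the map and classification workflows is installed
at `inst/cli/optimammo.R` (`map` and `classify` subcommands).

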