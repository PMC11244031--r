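---
title: "Object-based hyperspectral classification: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-based hyperspectral classification: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `hyperobia`, the numerical
conventions behind every stage, what the synthetic-scene generator does and
does not emulate, and the package's known limitations. All quantitative
claims about behaviour are made (and verified) by the test suite and
`scripts/acceptance.R`, not here.

## The pipeline

The package classifies vegetation species from calibrated UAV hyperspectral
reflectance cubes using object-based image analysis: the scene is
partitioned into segments (objects), features are aggregated per object,
and objects — not pixels — are classified. Six feature families are
available:

* **OS** — original per-band reflectance,
* **FOD / SOD** — first- and second-order Grünwald–Letnikov derivative
  spectra,
* **TF** — 24 GLCM texture layers (8 statistics × first 3 principal
  components),
* **VI** — 15 narrow-band vegetation indices,
* **GF** — 14 geometric features of the object outline.

Ten fixed family combinations ("schemes") are compared via
`scheme_table()`; scheme 10 uses all of OS, FOD, TF, VI and GF.

## Spectral differentiation

The Grünwald–Letnikov fractional derivative of order $\nu \ge 0$ is the
backward sum
$$ d^\nu f(k) \approx h^{-\nu}\sum_{m\ge 0} w_m\, f(k-m), \qquad
   w_m = (-1)^m \frac{\Gamma(\nu+1)}{m!\,\Gamma(\nu-m+1)}. $$
Weights are computed by the multiplicative recurrence
$w_m = w_{m-1}(m-1-\nu)/m$, which is algebraically identical to the
Gamma-ratio form but avoids Gamma poles and overflow; the test suite checks
the recurrence against direct Gamma evaluation to $10^{-9}$. Orders 1 and 2
reproduce ordinary first/second backward differences exactly. The
derivative is taken on the band-index grid ($h = 1$ by default), applied to
a whole cube as a single lower-triangular Toeplitz matrix product. Leading
samples can be kept (`truncate`, default) or blanked (`mark_invalid`).

## Vegetation indices

The 15-index catalogue ships as JSON (`inst/extdata/vi_catalogue.json`)
with explicit wavelengths and arithmetic expressions. Required wavelengths
are resolved by nearest-band lookup with a 15 nm tolerance, ties broken
toward the lower wavelength. Two formulas circulate in the literature in
typographically ambiguous variants; the catalogue uses the canonical forms

* **MCARI2** with denominator
  $\sqrt{(2\rho_{860}+1)^2 - (6\rho_{860} - 5\sqrt{\rho_{680}}) - 0.5}$,
* **TDVI** $= 1.5\,(\rho_{860}-\rho_{680}) /
  \sqrt{\rho_{860}^2 + \rho_{680} + 0.5}$.

Division by zero follows a configurable policy (`nan` propagates,
`error` aborts).

## Texture and window selection

Each of the first three principal-component images (eigendecomposition of
the band covariance; component signs fixed by making the
largest-magnitude loading positive) is quantized to 32 grey levels by
global min–max scaling and summarised in a sliding window by a symmetric
co-occurrence matrix accumulated over the four unit offsets (0°, 45°, 90°,
135°). Windows are clipped at image borders; missing pixels are excluded
from pair counting; the correlation statistic is defined as 0 where the
marginal variance vanishes. The compiled kernel is verified against a
brute-force pair-enumeration oracle written independently in R.

The window size is selected by sweeping all odd windows from 3 to 45 and
computing all pairwise Jeffries–Matusita distances between per-class
texture vectors. The chosen window is the smallest one whose *minimum*
pairwise J-M increases by less than 0.01 at each of the next two larger
windows — a plateau rule that formalises "separability has stabilised";
if no plateau exists the largest window is used.

J-M distance is $2(1 - e^{-B})$ with the Gaussian Bhattacharyya distance
$B$; sample covariances are regularized by $+\varepsilon I$,
$\varepsilon = 10^{-6}\,\overline{\mathrm{diag}}$.

## Objects and geometry

Per-object features are arithmetic means over the object's pixels; object
labels are the majority pixel class, ties broken toward the lowest class
ID. The 14 geometric features model pixels as unit squares: the
second-moment ellipse adds $1/12$ per-pixel variance so a $w \times h$
rectangle yields axis lengths proportional to $w$ and $h$ exactly;
perimeters count pixel edges; the convex hull is taken over pixel corners;
the oriented bounding box comes from a rotating-calipers scan of hull
edges; holes are 8-connected background components not touching the
outside. Definitions follow common OBIA attribute semantics; exact
equivalence with any proprietary tool is not claimed. A deterministic
region-merging segmentation stand-in is provided for self-contained runs;
externally produced segment rasters are accepted everywhere.

## Feature selection

The GA wrapper uses binary chromosomes over feature columns, tournament
selection (k = 2), uniform crossover with probability 0.9, elitism 1 and
20 generations with a population of 50. The mutation probability 0.2 is
interpreted **per individual** (one uniformly chosen bit flips); a per-bit
rate of 0.2 would rerandomize a fifth of the genome every generation and
prevent convergence in 20 generations — `mutation_mode = "per_bit"` exposes
that reading. Fitness is stratified 5-fold cross-validated overall
accuracy of a small KNN (k = 5) by default (the final assessment classifier
is configurable and independent); evaluations are memoized by mask, empty
masks are repaired, and the best mask ever seen is returned, which makes
the best-fitness history non-decreasing by construction under elitism.

## Classifiers and metrics

* **KNN**, k = 17, with a deterministic vote tie-break: among tied majority
  classes, the class of the nearest neighbour wins.
* **SVM**, RBF kernel, C = 200 (via `e1071`).
* **Random forest**, 500 trees (via `randomForest`, seeded).
* **ANN**: one hidden layer of 64 sigmoid units, softmax output,
  cross-entropy loss, trained by full-batch Adam
  ($\beta_1 = 0.9, \beta_2 = 0.999$, learning rate 0.05, 100 epochs). It is
  implemented in the package because the pinned optimizer is Adam.

KNN, SVM and the ANN operate on z-scores fitted on the training split
only. Metrics from the confusion matrix (rows = truth): overall accuracy
= trace/total, average accuracy = mean per-class recall, and Cohen's kappa
with chance agreement $p_e = \sum_c \mathrm{row}_c\,\mathrm{col}_c /
N^2$.

The salt-and-pepper index of a predicted map is the fraction of pixels
whose label differs from the majority of their 8-neighbourhood (ties
toward the lowest class) — a scalar proxy for the isolated-pixel noise
that object-based maps suppress by construction.

## The synthetic scene generator — scope of emulation

Real flight campaigns cannot ship inside a package, so all end-to-end
behaviour is exercised on seeded synthetic scenes designed to reproduce
the *qualitative regime* of canopy-species mapping:

* four classes whose mean spectra pair up (two pairs differing mainly by a
  small red-edge shift), so spectral confusion is concentrated within
  pairs;
* a patchwise object layout (Voronoi cells of a Poisson point process,
  each class guaranteed at least two patches);
* class-specific multiplicative texture (smoothed Gaussian fields with
  per-class correlation length 1–8 px and amplitude 0.03–0.12), so texture
  carries real discriminative information;
* a ±10% illumination ramp;
* additive per-band sensor noise, s.d. 0.03 reflectance by default — a few
  percent of full scale, typical of narrow-band UAV push-broom sensors.
  This is the term that produces salt-and-pepper errors in pixel-based
  maps and that per-object averaging suppresses; with markedly less noise,
  pixel and object classification become indistinguishable and the
  comparison degenerates.
* reflectance clamped to $[10^{-3}, 1.5]$: calibrated vegetation
  reflectance is never exactly zero, and the floor keeps reciprocal-band
  indices (e.g. CRI2) finite under additive noise.

The generator does **not** emulate sensor spectral response functions,
atmospheric or BRDF effects, georeferencing error, mixed pixels at object
boundaries, or real segmentation error (synthetic objects are class-pure
by construction). Accuracy numbers obtained on synthetic scenes therefore
bound the pipeline's mechanics, not its field performance.

Problem sizes used in the tests and in `scripts/acceptance.R`
(e.g. 200 × 200 px / 60 bands for the single-scene run; 128 × 128 px /
40 bands / expected patch diameter 8 px for the ten-seed object-vs-pixel
comparison, giving a few hundred objects per scene) are the package's own
choices, set so the suite runs in minutes on one CPU while keeping
training-set sizes sensible in both modes.

## Determinism

Every stochastic step takes an explicit integer seed and restores the
global RNG state afterwards (`with_seed`); JSON reports are written with
fixed numeric formatting, so any CLI command rerun with the same config
and seed is byte-identical. ENVI cube round trips are bit-exact (64-bit
float); TIFF round trips are exact at 32-bit float precision.

## Limitations

* The segmentation stand-in is intentionally simple (single-feature region
  merging on PC1); production use should supply an external segmentation.
* Geometric features assume modest object sizes (convex hull and oriented
  bounding box are computed per object in R).
* The GA wrapper's runtime grows with population × generations × CV folds;
  the memoized KNN fitness keeps the defaults tractable, but wrapping the
  SVM or forest is substantially slower.
* Band-grid handling assumes strictly increasing wavelengths and nearest-
  band VI lookup within 15 nm; grids coarser than ~30 nm cannot evaluate
  the narrow-band indices.
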