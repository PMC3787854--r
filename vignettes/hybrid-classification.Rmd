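---
title: "Hybrid hyperspectral classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid hyperspectral classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridhsi)
```

## The problem

Narrow-band endoscopic imaging of the larynx produces hyperspectral image
stacks: 30 co-registered monochromatic frames spanning 390–680 nm in 10 nm
steps, so that every pixel carries a 30-component reflectance spectrum.
Lesions of the vocal-cord mucosa — hemorrhagic polyps, leukoplakia — differ
spectrally from healthy mucosa, but per-patient spectral variability and
strongly inhomogeneous illumination make fixed reference libraries
unreliable. `hybridhsi` implements a two-phase *hybrid* classification:

1. **Unsupervised phase (training image).** A hierarchy of endmember
   signatures is selected directly from the image, pixels are clustered
   around them, and the mean spectrum of each cluster is extracted.
2. **Supervised phase (second image, same diagnosis).** The cluster-mean
   endmembers transfer to a new image of the same tissue type, which is
   classified by the spectral angle mapper (SAM); the clusters known to
   represent pathological tissue are collapsed to a binary decision map and
   validated against a reference mask.

No training labels are needed on the second image: the only supervision is
the designation of which clusters are pathological on the first.

## The unsupervised phase

### Endmember selection

Under the linear mixture model (LMM) a pixel spectrum $R$ is a weighted sum
of component signatures,

$$R = f_1\mu_1 + f_2\mu_2 + \dots + f_N\mu_N,$$

with $f_n \ge 0$ the surface proportion of component $n$. The selection
stage builds the signature hierarchy greedily:

* **Seed.** Signature 1 is the spectrum of the pixel maximizing
  $\sum_b R_b^2$ — the "strongest" reflector in the scene.
* **Successors.** Signature $k$ is the pixel spectrum most separable from
  signatures $1..k-1$. Separability of a candidate from a *single* previous
  signature is its squared Euclidean distance, summed over bands. For
  $k \ge 3$ the aggregation over multiple previous signatures is a genuine
  design choice: we default to **max–min** (farthest-point sampling:
  maximize the minimum squared distance to every already-selected
  signature), because it enforces separation from *each* existing endmember
  rather than from their aggregate, which is what "high intra-cluster
  similarity and low inter-cluster similarity" demands. A **max–sum** rule
  (maximize the summed squared distances) is available via `rule =
  "max_sum"`; the rule used is recorded in `selection_rule`.
* **Determinism.** Ties break at the smallest `(row, col)` in row-major
  order; pixels spectrally identical to an already-selected signature are
  never re-selected, and asking for more signatures than there are distinct
  spectra is an error. Raw (uncalibrated) reflectance values are used in
  double precision, with no band weighting.

The default `n_signatures = 20` reflects the working regime of this
two-phase approach on laryngeal stacks: up to about 20 clusters at least
one class tracks altered tissue, while further clusters contribute
progressively less interpretable structure.

### Affinity maps and cluster assignment

Two parallel per-class "affinity" views are produced:

* **Abundances** (`unmix_lmm()`): per pixel, the least-squares mixture
  weights under a chosen constraint — non-negative (default, Lawson–Hanson
  NNLS via `pracma::lsqnonneg`), non-negative sum-to-one (the fully
  constrained variant, implemented by the standard augmentation of the NNLS
  system with a heavily weighted sum row, weight $10^4 \times \max|S|$), or
  unconstrained (QR; a rank-deficient signature matrix is flagged and
  solved by the SVD least-norm solution). These are inspection maps.
* **Posteriors** (`posterior_probabilities()`): class probabilities under
  an isotropic Gaussian per class, shared variance, uniform priors:
  $p_k \propto \exp(-\lVert R-\mu_k\rVert^2 / 2\sigma^2)$. The probability
  model behind "posterior probabilities" is not fully pinned down by the
  procedure we emulate; this is the minimal model that uses only the
  information the selection stage produces (the signature vectors), and its
  maximum-posterior assignment reduces to nearest-signature-in-Euclidean-
  distance, independent of $\sigma$ — a property the test suite checks
  across $\sigma \in \{0.1, 1, 10\}$.

Cluster assignment (`assign_clusters()`) takes the per-pixel argmax of the
posterior maps, ties to the lowest label, leaving no pixel unclassified.
`scale = "auto"` sets $\sigma$ to the median distance to the nearest
signature (with a fallback to 1 in the degenerate all-zero case); since the
assignment is $\sigma$-invariant, this choice only affects the softness of
the inspection maps. Softmaxes are computed with the max-shift
stabilization.

### Cluster profiles

`cluster_mean_profiles()` extracts one signature per nonempty cluster as
the per-band arithmetic mean over its pixels. These cluster means — not the
raw seed pixels — are what transfers to the second image: averaging
suppresses pixel noise and dilutes the influence of any single extreme
pixel.

## The supervised phase

The spectral angle mapper treats spectra as vectors in band space and
scores similarity by the angle between them,
$\theta(x, \mu) = \arccos\left(\langle x,\mu\rangle / \lVert x\rVert\,\lVert\mu\rVert\right)$,
with the cosine clipped to $[-1, 1]$ to absorb floating-point overshoot.
Because a multiplicative illumination change rescales a pixel spectrum
without rotating it, SAM labels are invariant to light/shadow contrast —
the property that makes transfer across differently illuminated
images viable. `sam_classify()` assigns each pixel to the
minimum-angle reference (ties to the lowest label). By default every pixel
is assigned; an optional `threshold` (radians) leaves pixels whose winning
angle exceeds it unclassified, for target-detection use. Zero-spectrum
pixels have no defined angle: label 0, angle `NA`.

All cluster profiles transfer, and the pathological classes are then named
on the transferred ids. Designating which clusters are pathological is, in
clinical use, an expert judgement; `suggest_target_labels()` provides a
mechanical stand-in that selects every cluster whose pixel precision
against a reference mask reaches `min_overlap` (default 0.5 — a cluster
mostly inside the lesion is a lesion cluster; the value is an artifact
decision, not a measured constant). `binarize()` collapses the target
classes to the binary decision map.

## Validation

`confusion()` tallies TP/FN/FP/TN over all pixels (no border exclusion —
no evaluation mask beyond the reference is defined), and
`detection_metrics()` derives

* sensitivity $= tp/(tp+fn)$,
* specificity $= tn/(tn+fp)$,
* bias $= (tp+fp)/(tp+fn)$ — detected positives over true positives; 1 is
  ideal, above 1 overestimates the lesion extent, below 1 underestimates.

Raw double-precision values are kept; the print method and JSON display
strings round percentages to 2 d.p. and bias to 4 d.p.

## The synthetic phantom generator

No in-vivo stacks accompany this package, so `phantom_spec()` /
`generate_phantom()` produce synthetic endoscopic phantoms that emulate the
*statistical structure* the pipeline must cope with:

* a dominant background tissue and elliptical/blob lesion regions with
  distinct per-band mean profiles;
* a smooth strictly positive multiplicative illumination field (linear
  gradient, default peak deviation 0.25, plus a mild radial vignette,
  default 0.15) — multiplicative because that is the disturbance SAM is
  meant to absorb;
* additive Gaussian sensor noise, default SD 2% of the mean signal,
  truncated at zero (Poisson shot noise is available behind
  `noise_model = "poisson"` but off by default so tests stay deterministic
  under a single seed mechanism).

The built-in profiles (`builtin_profile()`) are documented synthetic
constants on the 390–680/10 nm grid: `polyp_like` is constant to 580 nm
then rises with decreasing slope; `leukoplakia_like` is bright and nearly
flat; `mucosa_like` rises smoothly across the range. Their pairwise
spectral angles (0.14–0.25 rad) were computed once from these constants.
They are shaped after qualitative descriptions of laryngeal tissue classes,
**not** measured patient spectra: passing phantom tests demonstrates that
the pipeline machinery recovers planted structure under illumination and
noise, not that it would reach any particular accuracy on real mucosa,
whose spectral variability between patients is precisely the hard part.
Other real-data features deliberately not emulated: absorption/scattering
physics (hemoglobin bands), specular highlights, inter-band motion,
camera nonlinearity.

The default phantom is 128×110×30 — seconds-scale to process, with an
aspect ratio echoing typical cropped endoscopic frames (368×322).

## Numerical and interface choices

* Pixel coordinates are 1-based `(row, col)` and `crop_cube()` ranges are
  1-based inclusive, matching R matrix indexing throughout.
* TIFF cubes are written as 32-bit pages scaled to the cube maximum with a
  JSON sidecar (wavelengths, scale, metadata); ENVI BSQ/BIL uses 64-bit
  floats and round-trips exactly; RDS is the lossless archive format used
  for byte-identical reproducibility checks.
* When no wavelength metadata exists and none is supplied, an even
  390–680 nm grid is assumed and recorded in `meta$wavelengths_assumed`.
* Reflectance is used as recorded; no white-reference or flat-field
  calibration is applied, and none is assumed by any stage (SAM does not
  need it; Euclidean clustering inherits whatever units the camera used).
* All randomness lives in the phantom generator and is driven by the seed
  in its spec; the analysis pipeline is fully deterministic, so a run
  manifest (config, package version, content hashes) suffices to reproduce
  outputs byte-identically.

## Problem sizes in the test suite

Oracle-equivalence properties (selection, SAM, assignment, confusion) are
verified against exhaustive per-pixel scans on ~220 random instances up to
12×12×6. Mixture recovery uses noise-free synthesized cubes (tolerance
1e-4); the sum-to-one solver is checked against a dense grid search over
the 2-simplex at step 0.01. The end-to-end transfer property runs on the
full 128×110×30 phantom pair at 2% noise and requires sensitivity ≥ 0.80
and specificity ≥ 0.90; under the default conditions it attains 1.00/1.00.
Smaller 48×40 phantoms drive the pipeline and artifact tests.

## Known limitations

* The posterior model is an explicit design choice (see above); other
  plausible models (e.g. abundances as likelihood inputs) would give the
  same hard assignment only in special cases. `assign_clusters()` on
  abundance maps is available for that sensitivity analysis.
* Endmember selection by extremal pixels is noise-seeking by construction:
  the seed is the brightest pixel and successors are outliers. Cluster
  means repair much of this, but heavy-tailed noise would call for robust
  alternatives (not implemented).
* `suggest_target_labels()` needs a reference mask on the *training*
  image; fully automatic lesion discovery is out of scope.
* The number of clusters is fixed by the user (default 20); no automatic
  model selection is attempted.
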