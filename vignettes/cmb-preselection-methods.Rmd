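---
title: "Preselecting subjects with cerebral microbleeds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preselecting subjects with cerebral microbleeds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmbselect)
```

## The problem

Cerebral microbleeds (CMBs) are small (2–10 mm) round haemosiderin deposits
that appear as well-defined hypointense lesions on T2\*-weighted gradient
echo (GRE) and susceptibility-weighted (SWI) MRI. In large cohorts, manually
screening every subject for CMBs is infeasible; a useful compromise is
*subject-level preselection*: automatically flagging the subjects likely to
contain CMBs so that manual rating effort is spent where it matters.
`cmbselect` implements a computationally light preselection pipeline:

1. **Vessel/sulci removal.** Veins, sulci and other elongated dark
   structures are the dominant CMB mimics. They are detected from slice-wise
   Frangi vesselness and structure-tensor features by 2-class k-means
   clustering and replaced by inpainting from the unmasked neighbourhood.
2. **Voxel-wise candidate detection.** Seven per-voxel features (intensity,
   exponential of the standardized intensity, CLAHE, mean fast radial
   symmetry transform over radii 2/3/4/6 voxels, principal structure-tensor
   eigenvalue, blobness, Laplacian-of-Gaussian), each max-normalized per
   image, feed a calibrated radial-basis SVM; the probability map is
   thresholded at `th_prob = 0.8`.
3. **Shape filtering.** 26-connected candidate clusters are kept only if
   5 mm³ < volume < 120 mm³, ellipticity < 0.2, solidity ≥ 0.6 and
   2 mm < diameter < 10 mm (all in physical units).
4. **Subject decision.** A subject is called CMB-positive when the surviving
   candidate count strictly exceeds `Th_NCMB` (defaults 35 for SWI, 30 for
   GRE; configurable, and far lower values are appropriate for clean
   synthetic data).

Evaluation uses subject-level TPR/specificity/accuracy and ROC curves, and
cluster-wise TPR with the average number of false-positive clusters per
subject (FPavg) on a free-response ROC, with one-voxel overlap defining a
cluster hit.

## Why a phantom generator

The clinical cohorts this class of pipeline is developed on are
access-restricted. The package therefore ships a first-class synthetic
generator (`phantom_spec()`, `generate_phantom()`, `generate_cohort()`) that
emulates the *geometry* of the problem: an ellipsoidal brain at a constant
background level, dark quasi-spherical CMBs, dark curved vessel tubes, dark
ribbons hugging the surface (sulci), an optional large haemorrhage blob, and
additive Gaussian noise, all on anisotropic 0.8 × 0.8 × 3 mm voxels
mirroring population-imaging SWI protocols.

Generator defaults, chosen once as the package's study conditions:

* `background_level = 100`, `noise_sd = 5` (5% of background, a clean but
  not noiseless acquisition);
* `cmb_contrast = 0.5`; CMB diameters 2.5–6 mm. The lower end guarantees at
  least a 3 × 3 in-plane voxel footprint at 0.8 mm pitch; the upper end
  respects the observation that CMB volume distributions are dominated by
  the microbleed (2–5 mm) range — a sphere beyond ~6.1 mm already exceeds
  the 120 mm³ volume criterion and would be rejected by design;
* CMB centers are snapped to slice-center planes: with 3 mm slices a 2.5 mm
  sphere can otherwise fall entirely between slices, i.e. be invisible even
  in the ground truth;
* `vessel_contrast = 0.8`, darker than CMBs: veins and flow voids bloom to
  near signal void on susceptibility-weighted contrasts, and this intensity
  separation is what the three clustering features can actually measure (see
  below);
* vessels are smooth, predominantly in-plane polylines: at 3 mm slice
  thickness a through-plane vessel contributes only point-like
  cross-sections that no slice-wise filter can classify as tubular;
* positive cohort subjects carry 2–6 CMBs each (`generate_cohort`'s
  `n_cmbs_range`), a realistic low-burden regime.

What the phantom does **not** emulate: tissue texture, bias fields, Rician
noise, phase/susceptibility physics, motion or Gibbs artefacts, and
anatomy-dependent CMB placement. Passing the package's benchmarks therefore
demonstrates internal correctness and recovery under idealized contrast, not
clinical-grade performance; thresholds such as `Th_NCMB` must be re-tuned on
any real dataset.

## Design choices in stage 1

The paperless parts of stage 1 were fixed as follows, after observing the
behaviour of the filters on phantoms:

* **All second-order filtering is slice-wise 2-D.** The linearity measure
  `l = |λ₁ − λ₂| / 2` is a two-eigenvalue (2-D) form, and 3–5 mm slices
  dwarf the in-plane resolution, so axial slices are the natural filtering
  domain.
* **Raw-intensity operating point.** Frangi's two parameters are
  `beta1 = 0.9` (line-vs-blob discrimination) and `beta2 = 20`
  (second-order structureness cutoff). `beta2` acts on the Frobenius norm of
  the σ²-normalized Hessian, which lives in native intensity units. On a
  standardized image that norm is ~5 and the contrast term
  `1 − exp(−S²/2β₂²)` stays linear, making the response proportional to
  squared contrast rather than shape. Stage 1 therefore runs on the raw
  image by default (`vessel_removal$on = "raw"`), where object responses
  saturate the contrast term and the filter discriminates by shape; a config
  switch restores the standardized variant.
* **Clustering geometry.** The 2-means step sees three features (vesselness,
  λ₁, linearity) scaled to unit variance. Cluster centers are estimated on
  the mask interior (in-plane erosion by a 7-voxel disc): the brain/air
  boundary of a skull-stripped image carries the strongest edges in the
  volume and otherwise captures the "structure" cluster for itself. All
  in-mask voxels — including surface sulci — are then assigned to the
  nearest center, and the cluster with higher mean vesselness is the vessel
  class.
* **Inpainting.** Masked voxels are replaced by the mean of their 3 nearest
  unmasked in-slice neighbours (physical distance, ties broken by scan
  order), processed shell-by-shell inward so thick masks fill from their
  rim; each filled voxel immediately becomes a source. A fully masked slice
  falls back to the neighbouring-slice mean with a warning.

## Design choices in stages 2–4

* **Classifier.** Radial-basis SVM with default `e1071` hyperparameters.
  Probability calibration is a Platt sigmoid fitted by logistic regression
  on a held-out 20% calibration split; the split is seeded, which keeps the
  whole training path bit-reproducible (the libsvm-internal cross-validation
  calibration draws from a process-global RNG and is not).
* **Training sample.** All truth-positive voxels plus 10 background voxels
  per positive, sampled uniformly within the brain mask per training
  subject; rows are capped (stratified) at 6000 so the quadratic-kernel fit
  stays in seconds at vignette problem sizes.
* **Feature normalization** divides by the per-image maximum *absolute*
  value: signed features (LoG, blobness, λ-derived maps) have meaningful
  negative extrema for dark lesions, so a plain maximum would be
  ill-defined. Maps are zeroed outside the brain mask first. Under a
  positive rescaling of the input every normalized map is unchanged.
* **CLAHE** uses 8 × 8 tiles per slice on the volume min-max rescaled to
  [0, 1], clip limit 0.01 (as a fraction of the per-tile histogram). Slices
  are replicate-padded to a tile multiple and cropped back.
* **FRST** accumulates only dark-symmetry votes (one radius step against the
  gradient), radial-strictness α = 2, gradient floor at the per-slice 5th
  percentile of gradient magnitudes, Gaussian spreading σ = r/2, and the
  mean is taken over radii. Per-radius outputs are not individually
  rescaled before averaging.
* **Ellipticity** is `1 − minor/major` principal-axis ratio from second
  moments of the component's maximal-area axial slice; with 3 mm slices,
  3-D moments would report spurious elongation for genuinely spherical
  2–5 mm lesions. Voxels enter the moments as uniform squares (their own
  d²/12 second moment included), so few-voxel candidates are not reported
  as artificially elongated and a symmetric disc scores exactly 0.
* **Solidity** counts voxel centers inside the 3-D convex hull of the
  component's voxel centers (an incremental hull with deterministic joggle,
  built in compiled code): volume / rasterized convex volume. On a filled
  convex lattice shape the two counts coincide and the descriptor is
  exactly 1. Single-slice or degenerate components fall back to the
  2-D convex area ratio on the maximal-area slice.
* **Diameter** is the exact maximum pairwise distance between voxel centers
  (the longest line through the candidate); components above 4000 voxels —
  three orders of magnitude beyond a plausible CMB, already rejected by
  volume — use the bounding-box diagonal instead to keep threshold sweeps
  linear-time.
* **Boundary semantics** follow the criteria wording strictly: open volume
  and diameter intervals, strict ellipticity bound, inclusive ("lower
  threshold") solidity bound.
* **Undefined metrics** (zero denominators) surface as `NA` with a flag,
  never as 0 or 1. A detection overlapping two truth clusters scores two
  true positives and no false positive, because cluster TPR counts truth
  clusters and a false positive is defined by overlapping none.
* **Knee point** of a count-threshold sweep is operationalized as the
  maximum Youden index (TPR − FPR).

## Degenerate inputs and numerical edges

Constant images are rejected where a mask or standardization is requested;
constant slices pass through CLAHE unchanged with a warning; degenerate
(constant-feature) clustering yields an empty vessel mask with a warning;
exponential-feature arguments are clipped at |p·x| = 50; Frangi scales or
FRST radii larger than a slice are skipped with a warning; a single-voxel
component has ellipticity 0 and diameter equal to the in-plane pitch.

## Problem sizes

The test-suite benchmarks use 64 × 64 × 16 phantoms (module tests,
determinism, monotonicity) and a 96 × 96 × 24 cohort of 40 test subjects
plus 8 training subjects for the end-to-end recovery benchmark, with
training capped as above. These sizes were chosen so the full suite runs on
a laptop-class single core in minutes while every stage operates well above
its degenerate regime.

## Known limitations

* The phantom's flat background makes the vessel/background clustering
  easier than on textured parenchyma; conversely its small CMBs (2.5–6 mm
  at 0.8 × 0.8 × 3 mm) are harder targets than large lobar macrobleeds.
* Slice-wise filtering cannot remove through-plane vessel segments; on real
  data those survive as point mimics and are the main reason the subject
  threshold `Th_NCMB` must stay well above zero.
* The subject decision ignores lesion location; anatomical rating scales
  (deep vs lobar) are out of scope.
* With `beta1 = 0.9`, Frangi blob suppression is mild; separation of CMBs
  from vessels in stage 1 leans on the intensity gap between venous voids
  and microbleeds. Where that gap is absent, CMB rims are partially painted
  over and detection relies on the surviving core.
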