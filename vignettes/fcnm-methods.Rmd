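---
title: "Coordinate-based network mapping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based network mapping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Case–control neuroimaging studies of psychiatric risk report group
differences as lists of peak coordinates in a stereotactic space, and the
peaks scatter widely across studies. Coordinate-based network mapping
asks a different question of the same data: rather than whether the peaks
co-localise, whether they fall on a *common functional network* — the set
of regions whose spontaneous activity is coupled to those locations in a
normative resting-state cohort. `fcnm` implements this procedure end to
end, from coordinate tables and 4D resting-state volumes to binary
"susceptibility network" masks, along with the similarity (Dice) and
atlas-composition statistics used to compare the resulting networks.

## The procedure

For each *contrast* (one reported group difference carrying one or more
peaks, all harmonised to MNI space):

1. **Seed construction.** A sphere of radius $r$ (default 4 mm) is placed
   at each peak; the union, intersected with the brain mask, is the
   contrast seed. Sphere membership is Euclidean distance from the voxel
   *centre* to the peak, in mm — stated explicitly because a 4 mm radius
   on a 3 mm grid is sensitive to the convention.
2. **Subject-level connectivity.** For every subject in the normative
   cohort, the Pearson correlation between the seed's mean time course
   and each in-brain voxel's time course is computed and Fisher
   z-transformed, $z = \operatorname{atanh}(r)$.
3. **Group statistic.** Across subjects, each voxel receives a one-sample
   t statistic $t = \bar z / (s_z / \sqrt{n})$ with $n - 1$ degrees of
   freedom.
4. **Thresholding.** One-sided (right-tail) p-values — only positive
   connectivity is biologically retained — are corrected by
   Benjamini–Hochberg FDR at $q$ (default 0.05) over the valid in-brain
   voxels and binarised.
5. **Overlay.** Within each disorder-by-modality group of contrasts, the
   binarised maps are averaged into a probability map (the fraction of
   contrasts containing each voxel), and voxels present in at least the
   overlay threshold (default 60%, inclusive) form the susceptibility
   network. Functional and structural networks of one disorder are
   additionally combined by voxelwise union.

Networks are compared by the Dice coefficient
$2\,|A \cap B| / (|A| + |B|)$ and decomposed against a canonical network
atlas as, per atlas network $k$, $|N \cap A_k| / |A_k|$ — the proportion
of the canonical network covered, which deliberately does not sum to one
across networks.

## Temporal preprocessing

The package implements the formula-level temporal cleaning that precedes
mapping; spatial preprocessing (slice timing, realignment, normalisation,
smoothing) is assumed done upstream, and synthetic data are generated
directly on the common grid.

* **Framewise displacement** uses the Power convention:
  $FD_t = \sum |\Delta d_t| + 50\,\mathrm{mm} \cdot \sum |\Delta
  \theta_t|$, translations in mm plus rotations (radians) converted on a
  50 mm sphere; $FD_1 = 0$. The commonly used $FD > 0.5$ mm scrubbing
  threshold is native to this convention, which is why it was chosen.
* **Nuisance design**: intercept; linear drift (the only detrending
  order); the Friston-24 expansion $[R, R^2, R_{t-1}, R_{t-1}^2]$ of the
  six rigid-body parameters with zero-padded first rows; one one-hot
  spike regressor per frame with $FD$ *strictly greater than* 0.5 mm;
  and the mean time courses over the brain (global signal), white-matter
  and CSF masks. Residualisation is ordinary least squares per voxel.
* **Band-pass** is an ideal frequency-domain filter on 0.01–0.1 Hz:
  Fourier coefficients outside the band (including DC) are zeroed. This
  is the fully deterministic rectangular filter of the standard
  resting-state toolchains, chosen over an IIR design for exact
  reproducibility.
* The default stage order is regression **then** filtering;
  `filter_first = TRUE` exposes the alternative but the default is the
  reference behaviour.
* Cleaning is applied to in-brain voxels; voxels outside the brain mask
  are set to zero and excluded from every downstream stage.
* Subject screening retains ages within 18–60 and motion below 2 mm
  translation and 2 degrees rotation (rotations stored in radians are
  compared in degrees).

## Coordinate harmonisation

Coordinates reported in Talairach space are converted to MNI with the
inverse of the Lancaster `icbm_spm2tal` affine — current best practice
for peaks from SPM-normalised analyses. The older Brett piecewise
transform is available behind `method = "brett"`; results differ by a
millimetre or two, which matters only at sub-voxel seed radii. Conversion
of records already in MNI space is the identity.

## The synthetic study generator

`sim_config()` / `simulate_cohort()` emulate the statistical structure
the analysis relies on, not fMRI physics:

* K mutually exclusive, contiguous spherical networks (radius 9 mm)
  inside an ellipsoidal brain on a reduced 30 x 36 x 30 grid at 3 mm —
  small enough that the full pipeline runs in minutes, configurable up to
  MNI-like sizes.
* Per subject and network, an independent standard-normal latent series;
  voxels of network $k$ observe $a \cdot \text{latent}_k +
  \varepsilon$, other in-brain voxels $\varepsilon$ alone, with
  $\varepsilon \sim N(0, \sigma^2)$ i.i.d. (optionally AR(1) with the
  marginal variance held at $\sigma^2$). The expected within-network
  voxel pair correlation is therefore $a^2 / (a^2 + \sigma^2)$ — the
  closed form the generator is tested against. Latents are independent
  *across subjects*: group consistency arises from shared network
  geometry, which is exactly the assumption the mapping procedure makes.
* Out-of-brain voxels are identically zero; they are never analysed.
* Motion traces are smooth centred random walks rescaled to 0.3 mm / 0.3
  degree peak amplitude, compliant with the screen by construction;
  `spike_prob` injects 1 mm single-frame excursions that exceed the
  scrubbing threshold.
* `plant_contrasts()` samples peaks from the voxel centres of a chosen
  network. The default reports them exactly at voxel centres because
  published peak coordinates *are* voxel centres of each study's
  analysis grid; optional jitter emulates grid mismatch between studies.
  With the strict centre-within-radius sphere rule, a sub-voxel radius
  (the 1 mm robustness sweep) only produces non-empty seeds when peaks
  sit at or near voxel centres, so the default also keeps that sweep
  well-posed.

What passing the planted-recovery tests does **not** show about real
data: the generator has no spatial autocorrelation, no 1/f or
physiological noise, no hemodynamic convolution, no inter-subject
anatomical variability, and its networks are compact blobs rather than
distributed systems. The tests validate the *machinery* — that each
stage computes what it claims and that the composition recovers a ground
truth under the model's own assumptions — not field performance.

## Numerical choices

* Correlations are clamped to $|r| \le 1 - 10^{-7}$ before `atanh` so
  self-correlated seed voxels stay finite.
* Voxels with zero temporal variance are propagated as invalid and
  excluded from the FDR multiplicity burden $m$, as are voxels invalid
  in any subject and voxels whose across-subject standard deviation is
  zero (no infinite t values).
* The overlay threshold is inclusive (a voxel in exactly 60% of
  contrasts is in the network); the overlay denominator is the number of
  contrasts in that disorder-by-modality group.
* The BH step uses `p.adjust(method = "BH")`; tests compare its
  selections against an independently coded step-up procedure.
* Voxel indices are 0-based and coordinates are mm in the grid affine
  frame (NIfTI sform convention); `mm_to_voxel()` rounds to the nearest
  voxel and flags, never clips, out-of-grid results.
* All randomness in the generator flows from a mandatory seed; analyses
  themselves are deterministic, byte-identical across reruns and
  invariant to the worker count used for per-subject maps.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the full procedure on the
reduced default grid: planted-network recovery with 40 subjects x 200
volumes and 10 contrasts x 5 peaks (radius sweep 1/4/7 mm, split-half
rebuild); FDR calibration on global-null cohorts of 30 subjects x 150
volumes (100 replicate cohorts in the test suite, 30 in the acceptance
script); generator correlation checks at 200 volumes with 400 sampled
voxel pairs. These sizes were chosen so each check estimates its
quantity with comfortable margin while the whole suite stays desk-scale.

## Known limitations

* No cluster-extent or permutation-based alternatives to voxel-level
  FDR; no negative-connectivity networks.
* No atlas resampling: the canonical atlas must already be on the
  analysis grid.
* Contrast t-maps are computed on all retained subjects; per-contrast
  subject subsets are not supported.
* The generator's realism limits noted above.
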