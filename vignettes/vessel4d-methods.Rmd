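---
title: "Segmenting the cerebral vasculature in 4D CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the cerebral vasculature in 4D CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Time-resolved (4D) CT angiography acquires a series of whole-brain volumes
during the passage of a contrast bolus. A voxel inside a vessel brightens
and fades as the bolus passes; static tissue, bone and air do not change.
`vessel4d` turns that temporal signature into a voxel-wise segmentation of
the full cerebral vasculature in three stages: coarse candidate selection,
random-forest classification of candidate voxels on 24 image features, and
morphological postprocessing. The package also ships the complete
evaluation suite used to score such segmentations and a synthetic 4D
phantom generator with exact ground truth, so the whole pipeline can be
trained, exercised and validated without clinical data.

## Temporal statistics: WTA and WTV

The time points of a dynamic protocol are acquired at different tube
exposures $E_i$ (mAs), and quantum noise — the dominant noise source in
clinical CT — scales as $1/\sqrt{E_i}$. Averaging with exposure-derived
weights $\omega_i = E_i / \sum_j E_j$ therefore maximizes the
signal-to-noise ratio of the temporal mean. With $I_{x,y,z,i}$ the
attenuation (HU) of voxel $(x,y,z)$ at time $i$:

$$\mathrm{WTA}_{x,y,z} = \sum_{i} \omega_i \, I_{x,y,z,i}, \qquad
\mathrm{WTV}_{x,y,z} = \sqrt{\sum_{i} \omega_i \,
  \bigl(\mathrm{WTA}_{x,y,z} - I_{x,y,z,i}\bigr)^2}.$$

The WTV — an exposure-weighted temporal standard deviation — is the
workhorse map: it is large exactly where contrast changes attenuation over
time, is parameter-free, and does not depend on the (irregular) temporal
sampling of the protocol. Candidate voxels are those with
$\mathrm{WTV} > \mu + k\sigma$, where $\mu,\sigma$ are the mean and
standard deviation of all WTV voxel values and $k = 1.5$ by default. The
comparison is strict (`>`); the boundary case has measure zero and the
choice is documented rather than meaningful. $\mu$ and $\sigma$ are taken
from the raw voxel values, not a binned histogram, which is exact where
binning would approximate.

## The feature set

Each candidate voxel is described by 24 features, in a fixed, versioned
column order:

| group | count | content |
|---|---|---|
| temporal | 2 | WTA, WTV |
| baseline | 1 | T0, the first (minimal-contrast) time point |
| anatomy | 1 | signed Euclidean distance (mm) to the intracranial-cavity border; negative inside, positive outside |
| local histogram | 8 | mean, std, mode, entropy of the WTV in 5×5×5 and 9×9×9 neighborhoods |
| geometry | 12 | Hessian eigenvalues of the WTV at scales 0.5, 1.0, 1.5, 2.0 mm |

**Local histograms.** A histogram of the WTV values inside a cubic
neighborhood around a voxel describes the contrast between that voxel and
its immediate surroundings, so even the smallest enhancing vessel stands
out against its own background — something a global threshold cannot do,
because it is dominated by the large vessels. The entropy is

$$E = -\sum_i p_i \log_2 (p_i + \varepsilon), \qquad \varepsilon = 10^{-4},$$

with $p_i$ the occupancy fraction of bin $i$; $\varepsilon$ sits inside the
logarithm (exactly as the formula is written) to guard the zero logarithm,
which gives a constant neighborhood the slightly negative floor
$-\log_2(1+\varepsilon)$ instead of 0, and caps the uniform-occupancy
maximum just below $\log_2 B$ for $B$ bins. Binning choices that the
formula leaves open were fixed as follows and are configurable:

* 32 bins spanning the neighborhood's own $[\min, \max]$ range. Local-range
  binning keeps the feature invariant to global intensity offsets and
  matches the comparison-to-surroundings intent; a flat neighborhood
  degenerates to one occupied bin.
* Mode = center of the most populated bin, ties broken toward the lowest
  bin index (deterministic output); a flat neighborhood reports the
  constant value itself.
* Mean and standard deviation come from the raw neighborhood values, not
  the binned representation — bin-free moments are exact, and only mode and
  entropy require bins. The standard deviation uses the population
  convention (divide by $n$), the image-processing norm.
* Image borders are replicate-padded so the feature maps keep the full
  grid.

**Signed cavity distance.** The intracranial cavity mask is an input (in
clinical use it comes from an atlas-based segmentation; the phantom
supplies an ellipsoid). A binary in/out feature would discard the internal
carotid arteries and jugular veins, which run *outside* the cavity, so the
feature is instead the Euclidean distance to the cavity border — computed
exactly in physical mm on the anisotropic grid (a Felzenszwalb–Huttenlocher
distance transform), negated inside the mask. The border is the set of
cavity voxels with a background 6-neighbor, so border voxels score 0.

**Hessian eigenvalues.** Second-order Gaussian-derivative structure at four
scales evenly spaced over 0.5–2.0 mm, covering the vessel calibers of
interest. Details the underlying formulation leaves open: $\sigma$ is
specified in mm and converted per axis to voxels ($\sigma/\mathrm{spacing}$,
anisotropic); second derivatives are scale-normalized by $\sigma^2$
($\gamma = 1$, the standard scale-space choice); eigenvalues are sorted by
ascending $|\lambda|$, the stable convention of vesselness-style features
(at a bright tube's center: $|\lambda_1| \approx 0$,
$\lambda_2 \approx \lambda_3 < 0$). Discrete derivative kernels are sampled
Gaussian derivatives, DC-corrected and normalized so that constants,
ramps and quadratics map to exactly 0, 1 and 1.

## Classifier and training scheme

A probability random forest (100 trees, maximum depth 30, via `ranger`)
predicts a vessel probability for every candidate voxel; non-candidates are
assigned probability exactly 0 — the candidate gate is absolute. Training
data come from annotation subvolumes: positives are a random 10% of the
annotated vessel voxels, negatives an equal-count sample drawn without
replacement from all non-annotated voxels inside the subvolumes (taken
literally: not restricted to candidate voxels). Training is
single-threaded and seeded, so models are bit-reproducible; one master seed
fans out to per-case sampling and forest construction, and the model
records its feature-column manifest and refuses mismatched feature
matrices at prediction time.

The operating point defaults to probability 0.5. Choosing it by visual
inspection of ROC curves is not reproducible, so `optimal_threshold()`
offers a Youden-J maximizer on validation data as the programmatic
alternative; `cmd_train()` reports per-fold AUC and Youden threshold from
leave-one-out cross-validation over cases (here: phantom instances — the
identical machinery applies to patients).

## Postprocessing

Two steps, in this order:

1. **Component filter.** 26-connected components smaller than 25 voxels are
   discarded (strict `<`: a 25-voxel component survives). At the protocol
   voxel size of 0.43 × 0.43 × 0.5 mm this floor corresponds to
   `component_volume_ul(25)` ≈ 2.3 µL; such specks are typically noise or
   eye/jaw motion outside the cranial cavity.
2. **Hole filling.** Large, fast-flowing vessels can be under-segmented at
   their core; iterative hole filling with a 3×3×3 kernel for up to 10
   iterations closes these. The reference method names only the kernel and
   iteration count, so the filling rule had to be fixed: a background voxel
   flips to foreground when a strict majority (14 of 26) of its box
   neighbors are foreground — the voting scheme of the standard ITK-style
   iterative hole filler. The vote threshold is configurable. Foreground is
   never removed, so the operation grows monotonically and is idempotent
   after convergence; a hollow 5³ cube interior fills in 2 iterations.

## Evaluation suite

`evaluate_segmentation()` computes, inside an optional subvolume:
Dice (1.0 when both masks are empty), Hausdorff distance (HD), modified
Hausdorff (MHD = max of the two directed mean boundary distances), 95th
percentile HD, contour mean distance (CMD), absolute volume difference
(AVD, % of the reference volume), and voxel-wise
sensitivity/specificity/accuracy. Boundary voxels are foreground voxels
with a background 6-neighbor; distances are voxel-center to voxel-center in
physical mm. HD and MHD are max-of-directed by definition; the directedness
of HD95 and CMD is not fixed by convention, and both here pool the two
directed distance sets (the common choice). Empty-vs-nonempty comparisons
raise errors rather than returning sentinels, which would silently corrupt
aggregate statistics.

Because annotations live in disconnected subvolumes, per-subvolume distance
statistics are combined with `combine_subvolumes()`: the mean for CMD, the
maximum for HD, MHD and HD95. Confusion statistics can exclude the 1-voxel
dilation band of the reference (3×3×3 kernel): annotations mark
high-confidence vessel voxels, not exact lumen borders, and the exclusion
forgives disagreement exactly there. It can only raise specificity and
never touches sensitivity (reference-positive voxels are never excluded);
overlap and distance metrics always use the full annotation.

## The synthetic phantom

`generate_phantom()` emulates the clinical acquisition that motivates the
pipeline, at desk scale:

* **Protocol.** 19 time points — one 200 mAs acquisition 5 s after
  injection, thirteen at 100 mAs every 2 s, five at 75 mAs every 5 s —
  at 0.43 × 0.43 × 0.5 mm voxels. The default grid is 64³ (a full-size
  512 × 512 × 320 grid is supported but never needed for validation).
* **Scene.** Soft-tissue background at 30 HU inside an ellipsoidal
  intracranial cavity, a 1000 HU skull shell, air outside; five tubular
  vessels (radii 0.9–1.8 mm, peak enhancement 300–400 HU) with
  gamma-variate time–attenuation curves. Arterial vessels enhance early
  and briefly, the posterior draining vessel late and broadly, so the
  temporal features face both dynamics. Partial-volume voxels on the
  1-voxel rim around each lumen get fractional enhancement.
* **Noise.** Additive Gaussian, per-time-point standard deviation
  $\sigma_i = 10\,\mathrm{HU} \times \sqrt{100/E_i}$ — the quantum-noise
  law anchored at 10 HU for 100 mAs, a realistic smooth-kernel brain CT
  noise level. A Poisson option would be the next refinement.
* **Annotations.** Five ~8 mm boxes, one per vessel, mirror
  subvolume-restricted annotation; the truth mask restricted to the boxes
  plays the role of the manual annotations.
* **Artifacts.** `inject_motion()` translates chosen time points
  (circularly, so reversing the shift restores the data exactly) while
  leaving the truth mask fixed, reproducing the WTV inflation over broad
  tissue regions that characterizes motion-degraded acquisitions.

What the phantom deliberately does *not* emulate: anatomically realistic
branching trees, beam hardening, spectral effects, in-vivo enhancement
curves, or inter-patient variability. Passing the phantom experiment
therefore demonstrates that the pipeline's machinery — temporal statistics,
features, classifier, postprocessing, metrics — is implemented correctly
and recovers tubular enhancing structure under protocol-realistic noise; it
does not certify clinical accuracy on patient data.

## Validation design and problem sizes

The test suite checks every computational primitive against an independent
oracle: WTA/WTV against triple-loop evaluation of their defining sums
(tolerance 1e-10), histogram parameters against direct patch computations,
distance transforms and all boundary metrics against exhaustive
pairwise search on 16³ grids (tolerance 1e-9), the candidate threshold
against the Gaussian upper-tail probability $\bar\Phi(1.5) \approx 0.0668$
on 10⁶ samples, and postprocessing against constructed masks where the
correct answer is known by design. The end-to-end experiment
(`phantom_experiment()`) trains on three 64³ × 19 phantom cases and
segments a held-out fourth — sizes chosen so the whole suite runs in well
under a minute on one CPU while every stage operates on non-trivial data.
Determinism is asserted end to end: identical seeds give bit-identical
volumes, models and masks.

## Conventions and known limitations

* Voxel indices are 1-based and subvolume boxes are inclusive on both
  ends — the native R array convention. (Fighting the host language's
  indexing invites off-by-one errors.)
* The time axis is the last array axis; spacing is (x, y, z) in mm.
  Exposures are not part of NIfTI/MetaImage headers and live in a sidecar
  config (`case.json`) keyed by time order.
* Both 4D storage layouts — one true 4D file or an ordered series of 3D
  volumes — load to identical objects.
* Inputs are assumed rigidly registered across time; registration itself,
  atlas-based cavity segmentation, and DICOM ingestion are out of scope.
* Masks are written as unsigned 8-bit labels; volumes with NaN are refused
  at write time rather than silently propagated.
* The forest is the only stochastic component at segmentation time and is
  frozen in the model file; probabilistic calibration of forest outputs is
  not attempted.
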