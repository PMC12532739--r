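---
title: "Methods: DEI-based shotgun pellet material differentiation"
author: "dectpellet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DEI-based shotgun pellet material differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dectpellet)
```

## The measurement model

Dual-energy CT acquires two co-registered volumes of the same object at two
tube voltages (here 100 and 140 kVp, or 80 and 140 kVp for the
size-robustness protocol). On the extended Hounsfield scale, a voxel's HU
value is $1000\,(\mu/\mu_w - 1)$, where $\mu$ is the linear attenuation
coefficient and $\mu_w$ that of water. Because $\mu(E) = (\mu/\rho)(E)\,\rho$
is material- and energy-dependent, the normalized two-energy contrast

$$\mathrm{DEI} \;=\; \frac{I_\mathrm{low} - I_\mathrm{high}}
                          {I_\mathrm{low} + I_\mathrm{high} + 2000}$$

is a material signature: it is exactly zero for water, small for materials
whose attenuation ratio to water is nearly energy-flat, and large for
mid-Z metals such as iron and copper whose photoelectric contribution decays
steeply across the diagnostic energy range. Writing
$r_i = \mu_\mathrm{material}(E_i)/\mu_w(E_i)$ and noting
$I_i + 1000 = 1000\,r_i$, the DEI of an ideal monoenergetic pair reduces to
the closed form $(r_\mathrm{low} - r_\mathrm{high})/(r_\mathrm{low} +
r_\mathrm{high})$, which `theoretical_dei()` evaluates from the packaged
NIST mass-attenuation tables; the package asserts the algebraic equivalence
of the two routes to $10^{-9}$ over a 30–150 keV grid.

The physics module predicts the *direction and ordering* of DEI contrasts.
It does not predict the measured DEI of high-Z pellets (lead, tungsten,
bismuth): a real polychromatic scanner saturates and beam-hardens on these
strongly attenuating materials, collapsing their measured DEI to near zero.
The package therefore treats measured per-material DEI distributions as
calibration inputs rather than deriving them from first principles, and the
attenuation tables are interpolated log–log between nodes (attenuation is
near power-law between absorption edges; K-edge discontinuities at W 69.525,
Pb 88.005 and Bi 90.526 keV are kept as paired nodes 1 eV apart so energies
remain strictly increasing).

## The automated pipeline

1. **DEI volume** (`compute_dei_volume()`): the formula above, voxelwise, in
   double precision. Voxels with $|I_\mathrm{low} + I_\mathrm{high} + 2000|
   < \varepsilon$ (default 1 HU) are masked invalid and zeroed instead of
   producing non-finite values; the case is impossible for gelatine or metal
   but is guarded so downstream statistics never see `NaN`.
2. **Threshold** (`threshold_mask()`): pellet candidates are voxels of the
   *high*-kVp volume strictly above 2000 HU. The comparison is strict, so a
   voxel exactly at 2000 HU is background.
3. **Erosion** (`erode_mask()`): each axial slice is eroded by a disk of
   4-pixel diameter — the 13 pixels of the 5×5 bounding box at Euclidean
   distance ≤ 2.0 from the center (shipped as a plain-text fixture).
   Erosion is 2D in-plane by design: voxels are strongly anisotropic
   (0.504 mm in-plane vs 1.0 mm slices), so a "4-pixel" 3D ball would be
   ill-defined. Stripping the partial-volume shell is what makes per-pellet
   mean DEI insensitive to pellet diameter.
4. **Labelling** (`label_pellets()`): 26-connected 3D components of the
   eroded mask, one per pellet. The most permissive connectivity is used so
   an eroded core spanning adjacent slices is never double-counted; 6 and
   18 are available in the configuration. Components fully erased by
   erosion produce no record. Optional voxel-count bounds
   (`min_voxel_count`, `max_voxel_count`, off by default) provide the
   size-filter hook for clinical volumes containing other dense objects.
5. **Per-pellet summaries** (`pellet_dei_stats()`): mean and SD of DEI over
   each component's valid voxels, centroid at voxel centers
   $(i-\tfrac12)\,\Delta$, and mean high-kVp HU.
6. **Group statistics** (`summarize_groups()`, `wilcoxon_matrix()`,
   `classify_category()`): per-material means/SDs/quartiles, pairwise
   two-sided Wilcoxon rank-sum tests, and category calls.

### Wilcoxon details

With the small group sizes involved (4–13 pellets), exact p-values matter.
The pairwise test uses exact enumeration whenever the pooled sample size is
at most 20 and there are no ties, and the tie-corrected normal approximation
with continuity correction otherwise; the diagonal is fixed at 1. The exact
branch is validated against exhaustive permutation enumeration for all
group sizes up to 7, and the whole matrix is invariant under monotone
transforms of the data, as a rank test must be. Raw p-values are reported,
mirroring standard practice for a single five-group comparison; a Holm
option exists but is off by default.

### Classification boundaries

DEI thresholds are protocol-specific (steel reads ≈ 0.21 at 100/140 kVp but
≈ 0.30 at 80/140 kVp), so category boundaries live in configuration tied to
a named profile, not in code. For the default 100/140 kVp profile: steel if
mean DEI ≥ 0.1995 (the midpoint of the reference copper 0.187 and steel
0.212 means), copper in [0.1, 0.1995), high-Z indeterminate below 0.1. Lead,
tungsten and bismuth are never separated — their attenuation ratios are too
similar at diagnostic energies — and steel alone carries the ferromagnetic
flag, the clinically actionable output for MRI safety. An optional buffer
half-width turns near-boundary values into "indeterminate" instead of
forcing a call.

## What the synthetic phantom emulates

No scanned raw data accompany the reference protocol, so the generator
(`generate_block()`, `default_phantom()`) produces gelatine-block volumes
whose *measured* statistics are reproduced by construction:

* **Geometry**: 70 × 70 × 150 mm blocks at 0.504 × 0.504 × 1.0 mm voxels;
  spherical pellets of 3 mm (and 4 mm for the steel protocol) diameter with
  seeded uniform-random centers at 20–120 mm axial depth and ≥ 10 mm
  pairwise separation, matching the embedding depths observed after test
  firing.
* **Calibration**: each pellet draws its interior DEI from
  $N(\mu_m, \sigma_m)$ with the per-material reference values
  (Fe 0.212 ± 0.006, Pb 0.008 ± 0.001, Cu 0.187 ± 0.002, W 0.012 ± 0.004,
  Bi 0.008 ± 0.002 at 100/140 kVp; steel 0.300 ± 0.002 at 80/140 kVp) and
  group sizes (5, 4, 13, 6, 8; 20 per steel block). The interior two-energy
  HU pair is then the exact algebraic inversion
  $H_1 = (H_2(1+d) + 2000d)/(1-d)$ at a common high-kVp anchor of 8000 HU.
  The anchor is a convention, not a physics claim: measured pellet HU is
  not reported by the protocol beyond exceeding the 2000 HU threshold, and
  a shared anchor isolates DEI as the discriminating quantity. Per-material
  anchors and a per-pellet anchor jitter are configurable.
* **Partial volume**: voxel pellet fractions are computed by 4× per-axis
  supersampled sphere rasterization (64 subvoxels per voxel), bounding the
  discretization error of a 3 mm sphere's volume below 2%; voxel HU blends
  pellet and gelatine values by that fraction independently at each energy.
  Boundary voxels are therefore DEI-biased toward gelatine, reproducing the
  partial-volume behaviour the pipeline's erosion step exists to remove.
* **Noise**: additive Gaussian, SD 15 HU, independent between energies and
  volumes — the simplest model consistent with filtered-back-projection
  noise at the reference dose. No noise correlation, scatter, spectrum or
  projection-domain physics is modelled; an optional cosmetic streak
  artifact is deliberately absent from the core model.
* **Background**: gelatine at (60, 50) HU for (low, high) — slightly denser
  than water, background DEI ≈ 0.0047. Config values, not physics claims.
* **Determinism**: one seeded stream per block with fixed draw order
  (pellet DEI → anchor jitter → low-kVp noise → high-kVp noise); identical
  spec and seed give bit-identical volumes and truth sidecars, and the
  generator restores the caller's RNG state.

Passing the phantom-recovery tests therefore demonstrates that the
*pipeline* (formula, threshold, erosion, labelling, statistics) is correct
and unbiased under realistic noise, partial volume and the printed group
sizes. It does not demonstrate robustness to beam hardening, streaks,
motion, or non-spherical fragments — none of which the generator emulates —
so performance on scanner data remains a claim about the method, not about
this validation.

### The 80/140 kVp size-robustness profile

The 3 mm and 4 mm steel blocks share a single material truth
(0.300 ± 0.002). This is a deliberate design choice: the two diameters are
the same metal, so any 3 mm vs 4 mm difference in recovered mean DEI must
be attributable to the pipeline (partial-volume handling), not to the
phantom. Under that shared truth the recovered relative difference is
≈ 0.1–0.2% (median over 10 seeds), comfortably inside the sub-percent
agreement reported for the physical experiment, whose two printed means
(0.300 and 0.297) differ by 0.8% and bound what residual size dependence is
acceptable.

### Orientation robustness

The rescan-robustness property is asserted for in-plane transforms: swapping
the x/y axes or flipping either in-plane axis of a generated block leaves
every recovered per-pellet mean DEI bit-identical, because the footprint and
connectivity are symmetric. Permuting the *slice* axis into the plane is not
an invariance of the method — erosion is intentionally 2D on anisotropic
voxels — and corresponds to no physical repositioning of an axially scanned
block, so it is not asserted.

## Numerical choices and degenerate inputs

* DEI volumes are double precision throughout; no intermediate rounding.
* The denominator guard (±1 HU) masks rather than errors; all-invalid
  components are excluded from statistics with a warning.
* Ties in the erosion/labelling stages cannot occur (boolean masks); label
  numbering follows first raster-scan appearance and is stable.
* Empty segmentations are a warning plus empty outputs, not an error — an
  operator scanning a pellet-free block should get a clean "nothing found".
* Rejection sampling of pellet centers aborts after 10,000 failed draws
  with an explicit error rather than looping forever on infeasible specs.
* Pellets overlapping (centers closer than the diameter) are permitted,
  blended by fraction weight, flagged in the truth sidecar and warned
  about; the reference layouts keep ≥ 10 mm separation so the case arises
  only in user-constructed specs.

## Problem sizes used in the shipped validation

The end-to-end material-recovery checks run the five full-size blocks
(139 × 139 × 150 voxels × 2 energies each) and the two 20-pellet steel
blocks, about 45 s in total. Supporting property suites use compact blocks
(e.g. 40–48 mm edges) for replicated runs — 100 seeded detection-fidelity
phantoms and 200 statistics-stage significance replicates — because pellet
detection and per-pellet recovery are local to each pellet and do not
depend on block extent.

## Known limitations

* Measured high-Z DEI values are calibration inputs; the physics module
  cannot and does not reproduce them (saturation/beam hardening).
* The Bi attenuation nodes adjacent to its K edge are the least certain
  entries of the packaged tables; nothing downstream depends on them.
* No watershed splitting of touching pellets: pellets closer than the
  erosion can separate merge into one component (flagged only via counts).
* No metal-artifact reduction and no DICOM reader; NIfTI plus a JSON
  sidecar is the interchange format.
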