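---
title: "Time-lapse HR-pQCT bone remodeling and mechanoregulation: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-lapse HR-pQCT bone remodeling and mechanoregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`remodelr` quantifies bone remodeling and its mechanical regulation from
pairs of calibrated 3D mineral-density images taken months apart. This
vignette explains the models and conventions the package commits to, why its
tunable parameters have the defaults they have, what the synthetic phantom
does and does not emulate, and where the method's real limits are. It states
no result that the package's tests and acceptance script do not themselves
compute.

## The pipeline and its assumptions

A subject run (`run_subject()`) executes a fixed order of stages:

1. **Rigid registration** of the later image onto the earlier one
   (`register_rigid()`), multi-resolution (3 pyramid levels, factor 2),
   minimizing the mean squared intensity error over the domain overlap. The
   later image is the moving one; the final resampling is cubic
   (Catmull-Rom) for densities and nearest-neighbour for masks, while the
   optimization itself samples with linear interpolation for speed.
2. **Mask generation** (`generate_masks()`): threshold + morphology
   segmentation — hole-filled largest component for the whole bone; the
   cortical compartment is the morphologically opened high-density shell
   (default criterion 450 mg HA/cm³, opening radius 2 voxels); trabecular is
   the remainder minus a 2-voxel transition band. This replaces
   contour-evolution segmentation with a reproducible, dependency-free
   construction validated against phantom ground truth.
3. **Dynamic morphometry** (`threshold_sweep()`): both images are denoised
   with the constrained Gaussian filter, binarized at every rung of the
   threshold ladder, and classified voxel-wise (formed / resorbed /
   quiescent) inside the common region; volume fractions are relative to
   baseline bone volume at each threshold.
4. **Micro-FE** (`build_mesh()`, `solve_compression()`): voxels become
   hexahedral elements; a 1% axial compression with bonded (high-friction)
   platens is solved matrix-free; per-element SED at the centroid gives the
   effective strain `sqrt(2 SED / E)`; the axial reaction gives apparent
   stiffness.
5. **Mechanoregulation** (`extract_surface_events()`, `cp_curves()`,
   `derive_thresholds()`, `ccr()`): surface remodeling events are binned at
   1% steps of normalized effective strain; conditional probability curves
   yield the resorption/formation dominance thresholds and the correct
   classification rate.

The analysis assumes rigid anatomy (no growth or deformation between
visits), calibrated densities on both visits, and isotropic voxels.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| voxel size | 0.0607 | mm | second-generation HR-pQCT protocol |
| threshold ladder | 200–920 by 120 | mg HA/cm³ | standard dynamic-morphometry ladder; 320 standardized, trabecular capped at 680 |
| filter (sigma, truncate, support) | 1.2, 0.8, 1.0 | voxels | the published constrained-Gaussian setting; a 3×3×3 kernel at these values |
| E_max, rho_ref | 10000 MPa at 1200 | MPa, mg HA/cm³ | linear density-modulus scaling, common voxel micro-FE practice |
| rho_min | 130 | mg HA/cm³ | marrow/soft tissue excluded from the mesh |
| nu | 0.3 | — | standard bone tissue Poisson's ratio |
| applied strain | 0.01 | — | the 1% high-friction compression test |
| CP bin width | 0.01 | normalized strain | 1% bins of the normalization constant |
| min bin occupancy | 10 | events | CP estimates from fewer events are noise |

"Constrained Gaussian" is interpreted as a truncated, renormalized separable
Gaussian: taps beyond `truncate*sigma` are dropped, the window is capped at
the hard `support` radius, and weights are rescaled to unit sum, so constant
images are exact fixed points. The kernel radius is
`min(ceiling(truncate*sigma), floor(support))`.

Fixed conventions (chosen once, needed for countable tests): binarization
uses `>=`; surfaces and mesh connectivity are 6-connected (face neighbours);
voxel indices are 0-based with physical position `origin + index *
voxel_size` (voxel-centre convention); out-of-domain resampling fills with
0 mg HA/cm³ (air/marrow), neutral under every threshold in the ladder.

One convention deserves emphasis: **out-of-grid voxels count as bone** when
deciding what is "surface". The scan stack truncates the shaft, and the cut
faces at the first and last slice are not biological surfaces; treating them
as surface floods the event set with spurious quiescence concentrated at
whatever strain the stack ends happen to carry.

## The event model and CP normalization

Events are: resorbed surface voxels; formed voxels face-adjacent to the
surface, inheriting the effective strain of the adjacent baseline bone voxel
(lowest linear index if several — formed voxels have no baseline element of
their own); and quiescent surface voxels. A quiescent surface voxel that is
face-adjacent to a formed voxel is *not* emitted as a quiescent event by
default: the site visibly formed, and double-counting it as quiescence makes
formation dominance mathematically unreachable (every formed event would
drag along at least one quiescent parent).

`cp_curves()` supports two conditioning conventions. With
`type_weights = "counts"`, per-bin probabilities are raw type frequencies.
With `"equal"` (the pipeline default), each event type's strain histogram is
normalized to unit mass before the bin-wise conditioning — equal priors for
formation, quiescence and resorption. At physiological event rates
quiescence outnumbers remodeling in every bin, so raw-count curves are
quiescence-dominant everywhere and no threshold exists; prior equalization
is what makes "the strain at which formation becomes the dominant outcome"
a well-defined quantity, and is the convention under which a CCR is
naturally compared with the 1/3 chance level of a three-class problem.

`derive_thresholds()` uses a persistence rule: formation must be the
strictly most probable type from the candidate bin through every later
occupied bin (and symmetrically for resorption from zero upward). A single
dominant bin in the middle of the lazy zone is noise, not a threshold; if no
persistent dominance region exists the threshold is `NA` — undefined is a
value, not an error.

## The synthetic phantom

`make_phantom()` builds a distal-radius-like object: a cortical annulus
(900 mg HA/cm³, outer radius 1.15 mm, ~6 voxel wall) around a three-axis
trabecular rod lattice (650 mg HA/cm³, 0.5 mm pitch, 0.2 mm rods) in marrow
(50 mg HA/cm³), with a linear taper of the radii along the shaft (a
metaphyseal flare, 12% end to end), Gaussian surface blur (partial-volume
emulation, sd 0.8 voxels) and additive Gaussian noise (sd 60 mg HA/cm³).
Three design choices are load-bearing:

* **The taper is not cosmetic.** A straight shaft with a periodic lattice is
  invariant under one-lattice-period longitudinal shifts, making
  registration ill-posed; the flare anchors the longitudinal position.
  Even so the cost landscape keeps aliased local minima, which is why
  `register_rigid()` scans the longitudinal translation exhaustively at
  every pyramid level (with a sub-voxel final scan) and, when neighbouring
  periods are within 5% in cost, prefers the candidate closest to the
  initial estimate — repeat scans are positioned from a scout view, so large
  axial offsets are a priori unlikely.
* **Generation happens on a z-extended grid** and is cropped to the field of
  view, so a misaligned follow-up "scan" windows real anatomy; resampling a
  cropped image instead would drag a zero-filled band through the image and
  bias the registration optimum.
* **Lattice pitch and rod width are chosen for the instrument, not for
  anatomy.** Rods are ≥3 voxels so they survive partial volume plus the
  constrained filter at the standardized threshold, and the pitch keeps the
  discrete lattice fraction close to the closed form
  `3 (t/a)^2 - 2 (t/a)^3` despite disk-lattice commensuration. The resulting
  trabecular volume fraction (~0.23) is denser than typical trabecular bone;
  the phantom trades anatomical realism for detectability at 61 µm in a
  desk-scale field of view.

`simulate_followup()` applies one interval of mechanoregulated remodeling,
one voxel deep: surface voxels below the rule's resorption threshold (in
normalized strain) are resorbed and surface-adjacent background voxels above
the formation threshold gain bone, each with probability
`event_rate * obedience`; sites where the rule forbids the action act anyway
with probability `event_rate * (1 - obedience)`. Ground truth (labels,
counts, transform, rule) is recorded before blur, misalignment and fresh
noise are applied.

The generator's default `event_rate` is 0.8 with `obedience` 0.9. That is a
verification-instrument setting, not physiology: with raw-count CP curves,
resorption can only dominate a bin if `event_rate * obedience > 0.5`, so
recovering rule thresholds from count-based curves requires most of the
eligible surface to act. The default *pipeline configuration*
(`run_config()`) instead simulates a realistic interval (`event_rate`
0.25), under which per-compartment formation/resorption fractions land in
the physiological range and registration is unconfounded — bulk
single-interval growth of most of the cortical surface on a tapered shaft
is, to a rigid-MSE criterion, nearly indistinguishable from a longitudinal
shift. The end-to-end default also drives the simulated remodeling with the
phantom's own micro-FE strain field rather than the axial surrogate ramp,
for the same reason: ramp-driven remodeling at a high event rate is a
systematic axial drift of the surface.

## What passing tests do and do not show

On noise-free, blur-free phantoms the pipeline is exact: classified voxel
counts equal ground truth at the standardized threshold, and the CP analysis
recovers the generating thresholds to within one bin. These checks validate
the machinery, not the imaging physics. With realistic blur and noise, an
isolated one-voxel formation event is attenuated below the 320 mg HA/cm³
threshold by the 3×3×3 filter (a direct consequence of the kernel weights),
so detection recall of scattered single-voxel events is intrinsically poor
at this resolution; only spatially coherent remodeling survives the imaging
chain. Consequently the noisy default run reports reliable remodeling
fractions, stiffness and strain distributions, while its mechanoregulation
thresholds may be undefined or unstable — a detection limit of
single-interval, single-voxel events at 61 µm, not a software defect. The
acceptance script therefore reports threshold/CCR recovery from noise-free
conditions alongside the noisy end-to-end quantities.

The phantom also does not emulate: plate-like trabeculae, cortical
porosity, beam hardening or scatter, scanner-specific noise spectra
(noise is iid Gaussian), or motion artifacts within a scan (repositioning
between scans is modelled; intra-scan motion grading is an input filter in
practice, not computed here).

## Numerical choices

* Registration: Nelder-Mead per level on scaled parameters (one unit ≈ one
  voxel of boundary motion), two restarts on coarse levels, relative cost
  tolerance 1e-12, iteration cap 300 per pass; the MSE is evaluated by a
  fused C++ kernel, on a stride-2 subgrid at the finest level during
  optimization and at full resolution for the reported final value.
  `converged` means the final full-resolution MSE does not exceed the
  initial one.
* Micro-FE: Jacobi-preconditioned conjugate gradients on the free degrees of
  freedom, matrix-free (one shared 24×24 unit-modulus element matrix scaled
  per element), relative residual 1e-6 by default (tests use down to 1e-13
  when comparing against dense solves); deterministic element ordering.
  Elements below `rho_min` are excluded; the mesh keeps the largest
  face-connected component spanning the bottom and top slices, since
  anything else cannot carry the axial load.
* SED is recovered at the element centroid (single-point), matching the
  dense-oracle comparison in the tests.
* Percentiles use linear interpolation between order statistics
  (`quantile` type 7).
* Problem sizes: the default phantom is 92×92×88 voxels (~0.6 Mvox) and the
  default pipeline configuration 52×52×64, chosen so a full subject run
  completes in minutes on one CPU; both are configurable.

## Known limitations

* Rigid registration only; no deformable component, so growth or fracture
  callus between visits violates the model.
* The density-modulus law and `rho_min` are configurable conventions; apparent
  stiffness scales accordingly and should be compared only within a fixed
  law.
* Compartment masks near the endosteal wall are ambiguous to about a voxel
  where trabeculae merge into the cortex; the transition band absorbs most
  but not all of this.
* The CCR compares events against a three-way strain rule with sharp
  thresholds; it is a summary of curve separation, not a goodness-of-fit
  statistic.
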