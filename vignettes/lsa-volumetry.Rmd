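---
title: "Quantifying lenticulostriate artery vascular volume: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lenticulostriate artery vascular volume: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Lenticulostriate arteries (LSAs) are sub-millimetre perforators arising from
the first segments of the middle and anterior cerebral arteries (M1/A1) that
supply the basal ganglia and the internal capsule. On 7T time-of-flight MR
angiography (TOF-MRA) they are visible but thin — one to five voxels in
diameter at typical acquisition resolutions (0.23 × 0.23 × 0.36 mm
anisotropic, or 0.40 mm isotropic). Classical morphometry counts stems and
branches by hand and measures the longest vessel on a projection image;
these measures are subjective and noisy across readers.

`lsavol` implements an alternative target quantity: the **vascular volume**
of the LSAs inside anatomically defined subcortical regions (putamen,
globus pallidus, caudate nucleus, posterior limb of the internal capsule),
defined as

> vascular volume = (number of suprathreshold voxels inside the region) ×
> (voxel volume),

where the voxel volume is the product of the three voxel edge lengths. The
pipeline is: multiplicative bias correction → multiscale Hessian vessel
enhancement → restriction to the region masks → adaptive binarisation by a
volume-ratio scheme → per-region volumetry and large-artery quality control
→ centerline morphometry (stems, branches, maximal length). Scan–rescan
reproducibility of any of these measures is assessed with the
absolute-agreement intraclass correlation ICC(A,1), and associations
between measures with Pearson correlation.

## Vessel enhancement

Enhancement is the multiscale line filter on the scale-normalised image
Hessian. At Gaussian scale $\sigma$ the Hessian is computed with
spacing-aware Gaussian-derivative kernels (derivatives per mm) and
multiplied by $\sigma^2$, the standard normalisation that makes responses
comparable across scales. With eigenvalues ordered
$|\lambda_1| \le |\lambda_2| \le |\lambda_3|$, a voxel on a bright tube has
$\lambda_2, \lambda_3 < 0$, and the response is

$$ V_\sigma = \left(1 - e^{-R_A^2 / 2\alpha^2}\right)\,
   e^{-R_B^2 / 2\beta^2}\,\left(1 - e^{-S^2 / 2c^2}\right), $$

with $R_A = |\lambda_2|/|\lambda_3|$ separating lines from plates,
$R_B = |\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$ penalising blobs, and
$S = \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}$ the structure strength.
The output is the voxelwise maximum over a log-spaced ladder of scales.

Parameters follow the convention of angiographic vesselness GUIs, in which
suppression strengths are entered as percentages and diameters in voxels:

| parameter  | meaning                              | default | unit    |
|------------|--------------------------------------|---------|---------|
| `d_min`    | minimum vessel diameter              | 1       | voxels  |
| `d_max`    | maximum vessel diameter              | 5       | voxels  |
| `n_scales` | scales, log-spaced over d/2 radii    | 5       | —       |
| `alpha`    | plate suppression (10% → 0.10)       | 0.10    | —       |
| `beta`     | blob suppression (40% → 0.40)        | 0.40    | —       |
| `contrast` | structure-strength scale $c$         | 100     | intensity |

Three conventions here were genuinely open and are therefore explicit,
configurable choices rather than guesses presented as ground truth:

* **Percentage-to-weight mapping.** Suppression percentages map directly to
  the exponential weights ($\alpha$ = plates/100, $\beta$ = blobs/100) and
  "vessel contrast" to $c$ in intensity units. Different tools hide
  different internal mappings; this one is the simplest and is surfaced in
  `vesselness_params()`.
* **Diameter-to-scale mapping.** $\sigma$ ranges over tube *radii*
  (`d_min/2` … `d_max/2` voxels), since the tube response peaks near
  $\sigma \approx$ radius. Scales are expressed in mm internally via the
  geometric-mean spacing, and each axis gets its own kernel width, which is
  how anisotropic grids are handled.
* **Scale normalisation.** The $\sigma^2$ factor is kept (as in the
  ITK-based tools used in the field). Its practical cost is discussed under
  *Limitations*.

## Bias correction

Ultra-high-field TOF images carry a smooth multiplicative inhomogeneity.
The corrector estimates the field as the Gaussian-smoothed (FWHM 40 mm by
default) log-intensity of the parenchymal foreground, iterating the
low-pass estimate until the residual field is flat (a single smoothing pass
is a low-pass filter, not a projection; iterating makes the correction
approximately idempotent, in the spirit of iterative correctors such as
N4). Bright vessel voxels — an Otsu split *within* the foreground — are
excluded from the estimate so the vasculature does not imprint on the
field. The stage is pluggable: volumes already corrected by an external
tool can skip it (`bias_fwhm = NULL`).

Two numerical guards: non-positive foreground voxels are clamped to the
smallest positive intensity (with a warning) before the log, and a constant
image is returned unchanged.

## Threshold selection: the volume-ratio scheme

Binarisation uses a deterministic, auditable formalisation of
threshold adjustment by volume ratios with stopping constant
$\Delta^* = 0.2\%$:

1. Candidate thresholds descend linearly over the in-ROI intensity range,
   in steps of `step_percent` (default 0.5) percent of the range.
2. At each candidate the vessel-to-ROI volume ratio — suprathreshold voxels
   over total ROI voxels, in percent — is recorded.
3. Walking from the top, vessels accrue slowly. The first step whose ratio
   change exceeds $\Delta^*$ marks the onset of parenchymal tissue; the
   previous candidate is selected, after backing off any sub-$\Delta^*$
   accrual contiguous with the onset (bounded by one $\Delta^*$ of
   cumulative mass), so the selection sits at the *top* of the parenchyma
   mode rather than one step inside it.

Candidates were deliberately **not** taken as intensity percentiles of the
ROI: with percentile candidates every step adds exactly `step_percent`
percent of the ROI voxels, so any step larger than $\Delta^*$ would stop
the walk immediately and the scheme could never traverse the vessel mode.
A ladder linear in intensity preserves the intended behaviour — on a
bimodal enhanced image the selected threshold falls in the gap between the
background and vessel modes (a property the test suite verifies by
exhaustive candidate enumeration), and the scheme is invariant under
affine rescaling of the intensities.

Degenerate inputs are rejected explicitly: a constant ROI is an error, and
if no step ever exceeds $\Delta^*$ the function asks for a smaller step
rather than returning an arbitrary threshold. The full candidate, volume
and ratio-change curves are returned for audit and are written into the
case report.

Extraction of the binary vessel mask is fully automatic by default (all
suprathreshold in-ROI voxels). When a seed voxel on an LSA is supplied, the
mask keeps only 26-connected components belonging to the seeded tree
(the seed's component plus components touching its one-voxel dilation),
which removes isolated suprathreshold noise specks; a seed that falls below
the threshold is moved to the nearest suprathreshold voxel within 5 voxels,
with a warning.

## Quality control

Cases in which a large artery (e.g. an M2 segment creeping along the
brain surface) leaks into the subcortical ROI must be excluded, since such
voxels dominate the vascular volume. `flag_large_vessels()` computes the
exact Euclidean distance transform inside the vessel mask and flags any
connected component whose maximal inscribed radius exceeds `d_max/2`
voxels (converted to mm by the mean spacing). Excluded cases remain in the
cohort table with their volumes — they are listed, never silently dropped.

## Morphometry on the centerline graph

The vessel mask is thinned to a one-voxel centerline by sequential deletion
of topologically simple border voxels in six directional sub-iterations.
Plain topology-preserving thinning erodes *open tube ends axially* (a
2×2-voxel beam can collapse almost entirely), so the thinning here anchors,
per connected component, (a) one root-side source voxel — nearest the
parent artery or seed, or the deepest voxel by inscribed radius — and (b)
the geodesic tips: local maxima of the within-mask geodesic distance from
that source. Topology preservation then guarantees the anchored curve
survives, and centerline lengths remain faithful to the tube ends.

Junction voxels (≥ 3 skeleton neighbours, merged when adjacent) and
endpoints become graph nodes with mm coordinates; chains become edges whose
arc length is the voxel polyline length. Terminal spurs shorter than two
voxels (a flag) are pruned — they are thinning artifacts that would inflate
branch counts — and pass-through nodes are absorbed so edges correspond to
anatomical segments.

The counting definitions mirror the field's reading conventions:

* a **stem** is a trunk directly attached to the parent artery — an edge
  incident to a root node (roots are nodes inside, or nearest, the
  parent-artery mask);
* a **branch** is a daughter vessel with no subordinate branches — a
  terminal edge ending in a non-root endpoint;
* an unbranched trunk counts as **both** one stem and one branch;
* the **maximal length** is the largest root-to-endpoint geodesic along the
  centerline, reported in cm. Measuring along the 3D centerline is
  strictly more faithful to "distance from the parent artery to the visible
  end" than a manual 2D projected measurement; for comparability a
  maximum-intensity projection is available (`project_mip()`, default a
  28 mm coronal slab), on which lengths can be read the traditional way.

Whether "branches" should include daughters deeper than one generation is
ambiguous in the printed definitions the field uses; the terminal-segment
convention is declared here because it is the only graph-computable reading.

## Statistics

`icc_agreement()` implements ICC(A,1) — two-way random effects, single
measurement, absolute agreement — from the two-way ANOVA mean squares, with
the 95% confidence interval by the F-distribution method with
Satterthwaite degrees of freedom. "Absolute agreement" alone does not pin
down a software model (several two-way forms exist); A,1 is the standard
absolute-agreement form for scan–rescan designs with k = 2, the result is
labelled with the variant, and the point estimate is checked in the test
suite against an independent `aov()`-based computation on random tables.
Perfect-agreement tables (zero error and zero column variance) return ICC
exactly 1 with a degenerate interval; zero total variance is an error, not
an ICC of 1. Pearson correlations use the two-sided t-transform on n − 2
degrees of freedom; summaries are mean ± sample (n − 1) SD.

## The synthetic phantom generator

The generator is first-class, tested code: every downstream stage is
validated against phantoms with known ground truth.

* **Vessel trees** are binary branching recursions: smooth polylines with a
  per-mm curvature bound, child radii scaled by `radius_ratio` (children
  never wider than the parent), branching half-angles drawn from a range.
  Defaults are chosen to emulate LSA morphology on a 0.4 mm isotropic grid:
  trunk radius 0.4 mm (the caliber of the larger perforators visible at
  7T), two generations, 8–14 mm segments, 25–50° half-angles, 5°/mm
  curvature. Growth is clipped to the grid with a warning, never silently.
* **Rendering** gives tube voxels the vessel intensity with a linear
  soft-edge falloff (0.4 mm, one voxel of partial-volume width), multiplies
  by a smooth bias field — heavily smoothed white noise rescaled to
  $[1-a, 1+a]$, emulating dielectric inhomogeneity at 7T without modelling
  coil physics — and applies Rician noise last (the magnitude-MR noise
  model; Gaussian is available as an option). Defaults: blood-to-tissue
  contrast 3:1 (300 vs 100), noise $\sigma = 15$, bias amplitude 0.2.
* **Ground truth** is defined *pre-noise* by the hard geometric rule "voxel
  center within the tube radius", which gives an unambiguous oracle for
  volume recovery; true per-region volumes are exact voxel counts times the
  voxel volume, and are additive over regions by construction.
* **Region masks** are four disjoint ellipsoidal stand-ins for the putamen,
  globus pallidus, caudate and internal capsule, positioned so a default
  tree crosses the putamen predominantly (as the real LSAs do); a
  parent-artery sphere at each trunk origin provides the rooting region.

What the phantoms deliberately do **not** model: inflow saturation and
flow-related enhancement physics, vessel wall signal, pulsation or motion
artifacts, atlas registration error, and anatomically realistic region
shapes. Passing phantom tests therefore demonstrates the correctness of
the computational pipeline — geometry, topology, arithmetic, determinism —
not the clinical accuracy of LSA volumetry on real scans.

All randomness flows from explicit integer seeds; equal seeds give
bit-identical phantoms, reports and bundles, which the test suite checks at
the byte level.

## Problem sizes and numerical choices

The validation suite uses 96³ voxel grids at 0.4 mm for cylinder-recovery
and curved-length checks, 80³ grids for a 20-seed tree-topology study
(stems and branches recovered exactly in all 20 under the default
diameters ≥ 2 voxels), 48³ grids for end-to-end pipeline and determinism
checks, and n = 200 simulated scan–rescan pairs for ICC calibration. These
sizes were chosen as the smallest grids on which vessels of the modelled
caliber are comfortably resolved.

Other numerical choices: Gaussian kernels are truncated at 4σ with
replicate boundary handling and exact zero-DC derivative kernels (a
constant image has identically zero vesselness); eigenvalues of the
symmetric 3×3 Hessian come from the trigonometric closed form, vectorised
in C++; the Euclidean distance transform is the exact two-parabola
(Felzenszwalb–Huttenlocher) algorithm with anisotropic spacing; connected
components use 26-connectivity throughout.

## Limitations

* **Noise-free images defeat count-based threshold selection.** The
  $\sigma^2$-normalised multiscale filter assigns small positive responses
  to a halo one to two scales wide around each tube. On real (noisy)
  images the walk stops at the top of the tissue-response mode and the halo
  above threshold is modest; on an idealised noise-free phantom the
  background response is exactly zero, the only detectable onset is the
  zero plateau itself, and the suprathreshold set keeps the entire halo —
  the acceptance script quantifies the resulting cylinder-volume
  overestimate (tens of percent, largest for thin tubes). This is a
  property of pairing scale-normalised enhancement with a count-based
  stopping rule, not of the implementation; variants that drop the
  $\sigma^2$ normalisation shrink the halo values below the lowest
  candidate and avoid it, at the cost of scale-biased responses.
* Thresholds are global per ROI; no local adaptivity.
* The centerline is voxel-resolution; sub-voxel centerline refinement and
  diameter profiling along the centerline are out of scope.
* Region masks are taken as inputs (pre-aligned or with a user affine);
  non-linear warping belongs to external registration tools, and only
  nearest-neighbour interpolation is offered for labels (they are
  categorical, so nothing else is admissible).
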