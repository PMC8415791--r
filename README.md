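# lsavol

Quantification of lenticulostriate artery (LSA) vascular volume in
subcortical regions of 3D time-of-flight MR angiography (TOF-MRA).

LSAs are the sub-millimetre perforating arteries that arise from the first
segments of the middle and anterior cerebral arteries and supply the basal
ganglia and internal capsule; their occlusion causes lacunar stroke.
Counting their stems and branches by hand is subjective and unstable, so
this package implements a volumetric alternative for researchers working
with high-field angiography: the **vascular volume** of the LSAs inside
anatomically defined subcortical regions,

> vascular volume = (suprathreshold voxels inside the region) × (voxel volume),

where the voxel volume is the product of the three voxel edge lengths
(e.g. 0.23 × 0.23 × 0.36 mm³). The pipeline is

1. multiplicative bias-field correction (iterative log-domain low-pass
   estimator, pluggable);
2. multiscale Hessian vesselness on the σ²-normalised Hessian with ordered
   eigenvalues |λ₁| ≤ |λ₂| ≤ |λ₃| and the line-filter response
   `(1 − exp(−R_A²/2α²)) · exp(−R_B²/2β²) · (1 − exp(−S²/2c²))`
   for bright tubes (λ₂, λ₃ < 0), maximised over a log-spaced scale
   ladder covering vessel diameters of 1–5 voxels
   (α = 0.10, β = 0.40, c = 100 by default);
3. restriction to region-of-interest masks (putamen, globus pallidus,
   caudate, internal capsule) supplied as NIfTI label images;
4. adaptive threshold selection by a volume-ratio scheme: candidate
   thresholds descend over the in-ROI intensity range and the walk stops at
   the first step whose vessel-to-ROI volume-ratio change exceeds
   Δ\* = 0.2%, returning the previous candidate;
5. per-region volumetry, large-artery quality control (maximal inscribed
   radius from the exact Euclidean distance transform);
6. centerline morphometry on a topology-preserving skeleton graph: stems
   (trunks attached to the parent artery), branches (terminal segments —
   an unbranched trunk counts as both), maximal root-to-tip geodesic
   length in cm, and 28 mm coronal maximum-intensity projections;
7. scan–rescan reproducibility via the absolute-agreement intraclass
   correlation ICC(A,1) with its F-based 95% CI, and Pearson correlations
   between volume and the conventional measures.

A seeded synthetic angiogram generator (`lsa_phantom()`) produces TOF-like
phantoms — branching vessel trees with known centerlines and per-region
true volumes, smooth multiplicative bias, Rician noise, and
subcortical-like region masks — so every stage is validated against ground
truth.

## Worked example

```r
library(lsavol)

ph  <- lsa_phantom(seed = 7)                    # 96^3, 0.4 mm, noisy + biased
rep <- run_case(phantom_case_config(ph))
rep
#> <lsa_case_report> phantom-7: 575 vessel voxels, 36.8 mm^3
#>   stems 1, branches 4, longest 4.23 cm

rep$selection
#> <threshold_selection> threshold 0.0366502 at step 188/200 (ratio 0.546% of ROI)

rep$volumes
#> <region_volume_report> 575 vessel voxels, 36.8 mm^3 (voxel 0.064 mm^3)
#>            region voxels volume_mm3   fraction
#>           putamen    477     30.528 0.82956522
#>   globus_pallidus     16      1.024 0.02782609
#>           caudate     15      0.960 0.02608696
#>  internal_capsule     67      4.288 0.11652174
```

The threshold walk stopped where parenchymal noise began to flood the
suprathreshold set (step 188 of 200, with 0.55% of the ROI above
threshold); 575 voxels at 0.064 mm³ each give 36.8 mm³ of vascular volume,
~83% of it in the putamen — the phantom's tree, like real LSAs, funnels
through the putamen. The graph morphometry found the generating tree's one
trunk (1 stem) and its four terminal daughters (4 branches), with a
4.23 cm root-to-tip centerline. Quality control passed: no segmented component exceeded the
1 mm inscribed-radius limit that flags large-artery contamination.

Scan–rescan agreement of repeated volume measurements:

```r
icc_agreement(cbind(c(18.2, 21.4, 16.9, 24.0, 19.5),
                    c(18.9, 21.1, 17.4, 23.2, 20.1)))
#> ICC(A,1) two-way random, absolute agreement
#> ICC = 0.971 (95% CI 0.772-0.997), n = 5 subjects, k = 2 measurements
```

A thin command-line wrapper ships in `inst/cli/lsavol`
(`lsavol synth --seed 7 --out case0/`, `lsavol run --config case.yaml`,
`lsavol cohort --glob 'cases/*.yaml'`).

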